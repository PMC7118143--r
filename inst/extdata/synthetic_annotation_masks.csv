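"cell_id","x","y"
1,43,49
1,44,47
1,44,48
1,44,49
1,44,50
1,44,51
1,45,46
1,45,47
1,45,48
1,45,49
1,45,50
1,45,51
1,46,45
1,46,46
1,46,47
1,46,48
1,46,49
1,46,50
1,46,51
1,47,45
1,47,46
1,47,47
1,47,48
1,47,49
1,47,50
1,47,51
1,48,44
1,48,45
1,48,46
1,48,47
1,48,48
1,48,49
1,48,50
1,48,51
1,49,44
1,49,45
1,49,46
1,49,47
1,49,48
1,49,49
1,49,50
1,49,51
1,50,44
1,50,45
1,50,46
1,50,47
1,50,48
1,50,49
1,50,50
1,51,44
1,51,45
1,51,46
1,51,47
1,51,48
1,51,49
1,51,50
1,52,45
1,52,46
1,52,47
1,52,48
1,52,49
1,53,45
1,53,46
1,53,47
1,53,48
2,44,46
2,44,47
2,44,48
2,45,45
2,45,46
2,45,47
2,45,48
2,45,49
2,45,50
2,46,44
2,46,45
2,46,46
2,46,47
2,46,48
2,46,49
2,46,50
2,46,51
2,47,44
2,47,45
2,47,46
2,47,47
2,47,48
2,47,49
2,47,50
2,47,51
2,47,52
2,48,45
2,48,46
2,48,47
2,48,48
2,48,49
2,48,50
2,48,51
2,48,52
2,49,45
2,49,46
2,49,47
2,49,48
2,49,49
2,49,50
2,49,51
2,49,52
2,50,46
2,50,47
2,50,48
2,50,49
2,50,50
2,50,51
2,50,52
2,51,48
2,51,49
2,51,50
2,51,51
3,46,44
3,46,45
3,46,46
3,46,47
3,46,48
3,46,49
3,46,50
3,46,51
3,46,52
3,47,43
3,47,44
3,47,45
3,47,46
3,47,47
3,47,48
3,47,49
3,47,50
3,47,51
3,47,52
3,47,53
3,48,42
3,48,43
3,48,44
3,48,45
3,48,46
3,48,47
3,48,48
3,48,49
3,48,50
3,48,51
3,48,52
3,48,53
3,49,41
3,49,42
3,49,43
3,49,44
3,49,45
3,49,46
3,49,47
3,49,48
3,49,49
3,49,50
3,49,51
3,49,52
3,49,53
3,50,41
3,50,42
3,50,43
3,50,44
3,50,45
3,50,46
3,50,47
3,50,48
3,50,49
3,50,50
3,50,51
3,50,52
3,50,53
3,51,42
3,51,43
3,51,44
3,51,45
3,51,46
3,51,47
3,51,48
3,51,49
3,51,50
3,51,51
3,52,43
3,52,44
3,52,45
3,52,46
3,52,47
3,52,48
3,52,49
3,52,50
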