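# Binding-region residue lists (pocket-union definition): Site 1 pools the
# three persistent lower-helix pockets, Site 2 the two upper-helix pockets.
S1:
- 3
- 4
- 5
- 6
- 47
- 49
- 50
- 51
- 52
- 53
- 54
- 56
- 57
- 58
- 59
- 60
- 61
- 62
- 63
- 64
- 66
- 67
S2:
- 11
- 12
- 13
- 14
- 15
- 41
- 42
- 70
- 71
- 72
- 73
- 74
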