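littlecat:demo: the little cat chases the mouse the little cat catches the mouse the big cat chases the little cat the little cat runs away from the big cat
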