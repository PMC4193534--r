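{"x11":39,"x10":91,"x01":237,"x00":5360,"a11":29,"a10":338,"a0":5360,"n":5727}
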