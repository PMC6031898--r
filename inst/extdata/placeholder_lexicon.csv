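token_id,category
meth_w1,meth_word
meth_w2,meth_word
meth_w3,meth_word
meth_w4,meth_word
meth_w5,meth_word
meth_w6,meth_word
meth_w7,meth_word
meth_w8,meth_word
neut_w1,neutral_word
neut_w2,neutral_word
neut_w3,neutral_word
neut_w4,neutral_word
neut_w5,neutral_word
neut_w6,neutral_word
neut_w7,neutral_word
neut_w8,neutral_word
meth_p1,meth_picture
meth_p2,meth_picture
meth_p3,meth_picture
meth_p4,meth_picture
meth_p5,meth_picture
meth_p6,meth_picture
meth_p7,meth_picture
meth_p8,meth_picture
neut_p1,neutral_picture
neut_p2,neutral_picture
neut_p3,neutral_picture
neut_p4,neutral_picture
neut_p5,neutral_picture
neut_p6,neutral_picture
neut_p7,neutral_picture
neut_p8,neutral_picture
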