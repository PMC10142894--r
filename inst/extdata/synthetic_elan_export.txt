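nod	12.40	13.60	nod bout
nod	45.00	45.80	nod
speech	50.00	60.00	talking
nod	130.25	131.00	nod
sleep	200.00	260.00	asleep
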