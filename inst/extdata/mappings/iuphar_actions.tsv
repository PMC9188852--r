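actions	category
Activation	1
Biased agonist	1
Binding	3
Competitive	3
Feedback inhibition	2
Full agonist	1
Inhibition	2
Irreversible inhibition	2
Mixed	3
Neutral	3
Agonist	1
Partial agonist	1
Antagonist	2
Inverse agonist	2
Potentiation	1
Channel blocker	2
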