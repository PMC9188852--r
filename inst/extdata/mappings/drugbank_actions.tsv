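action	category
agonist	1
partial agonist	1
activator	1
inducer	1
stimulator	1
potentiator	1
positive allosteric modulator	1
inhibitor	2
antagonist	2
blocker	2
negative modulator	2
suppressor	2
inactivator	2
downregulator	2
inverse agonist	2
antibody	3
binder	3
ligand	3
modulator	3
substrate	3
carrier	3
transporter	3
other	3
unknown	3
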