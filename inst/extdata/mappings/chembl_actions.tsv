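action_type	category
ACTIVATOR	1
AGONIST	1
ANTAGONIST	2
BINDING AGENT	3
BLOCKER	2
MODULATOR	3
NEGATIVE ALLOSTERIC MODULATOR	2
NEGATIVE MODULATOR	2
POSITIVE MODULATOR	1
RELEASING AGENT	3
STABILISER	3
INHIBITOR	2
PARTIAL AGONIST	1
INVERSE AGONIST	2
POSITIVE ALLOSTERIC MODULATOR	1
OPENER	1
ANTISENSE INHIBITOR	2
SUBSTRATE	3
SEQUESTERING AGENT	3
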