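gene	class
CANDIDATE_ACTIVATED_01	activated
CANDIDATE_ACTIVATED_02	activated
CANDIDATE_ACTIVATED_03	activated
CANDIDATE_ACTIVATED_04	activated
CANDIDATE_ACTIVATED_05	activated
CANDIDATE_ACTIVATED_06	activated
CANDIDATE_ACTIVATED_07	activated
CANDIDATE_ACTIVATED_08	activated
CANDIDATE_REPRESSED_01	repressed
CANDIDATE_REPRESSED_02	repressed
CANDIDATE_REPRESSED_03	repressed
CANDIDATE_REPRESSED_04	repressed
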