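ego01	s_ego01_01
ego01	s_ego01_02
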