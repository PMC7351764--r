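# default run configuration: wild-type preset, no overrides
preset: WT
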