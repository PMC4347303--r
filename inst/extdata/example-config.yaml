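# Example hierCP configuration: coupled network at half size with the
# default combined condition (non-replicate stimuli, feedback strength 1).
network:
  bFB: 1
  backgroundMode: global
  scale: 0.5
stimulus:
  coherence: 0
  sigma: 1
  durationMs: 2000
  replicate: false
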