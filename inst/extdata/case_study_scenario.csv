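"cas","concentration","unit"
"78-93-3","90","ppm"
"108-10-1","6","ppm"
"108-88-3","8","ppm"
"79-01-6","2.5","ppm"
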