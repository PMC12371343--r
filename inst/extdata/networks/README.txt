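Synthetic benchmark GRN topologies (authored for this package).

Six small signed networks matching the structural families used in
standard GRN-inference benchmarks (bifurcating, bifurcating-converging,
trifurcating, cycle, linear, long-linear). These are versioned package
fixtures, not copies of any upstream file: the bifurcating family has an
upstream activation chain feeding gene g3, which activates both arms of
a mutually inhibitory, self-activating toggle (g4/g5, plus g6 for the
trifurcating case); toggle state selects the branch. Files are edge
lists with columns Gene1,Gene2,Sign (+ activation, - inhibition).
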