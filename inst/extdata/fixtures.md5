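dcdbb5359fe42f80685e84260760b3d5  isolate_scores.tsv
91b4708c06cdcc5bb0565d5210039454  selected_traits.tsv
60e2d56664bd217f7ef98a8af0d7d671  compatibility_constraints.tsv
24883f184496320aabe122864574171e  peg_calibration.tsv
92ce52ea6fa4058d99950f2f85ce7b22  gene_categories.csv
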