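extdata
=======

mini_fate_network.tsv   Frozen wiring of the 10-node miniature cell-fate
                        fixture (same network that make_miniature_fate_network()
                        builds in code; kept as a file so the TSV dialect has a
                        bundled example and the fixture's wiring is versioned).

apl_network.tsv         NOT SHIPPED. Placeholder path for a user-supplied
                        transcription of the published 81-node / 416-edge /
                        8-module APL endogenous network. load_apl_network()
                        reads this path and stops with a notice when the file
                        is absent.
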