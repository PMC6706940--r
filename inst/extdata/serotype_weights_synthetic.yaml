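# SYNTHETIC placeholder serotype score weights.
#
# The serotype risk score requires one weight per DRB1/DQB1 serotype
# group. Published weight sets exist (log odds-ratio scale, highest for
# the DR3/DR4-DQ8 compound heterozygote); substitute such a set here for
# real analyses. These placeholder values only preserve the qualitative
# risk ordering and are used by the synthetic test suite.
DR3/DR4-DQ8: 4.0
DR3/DR3: 2.8
DR4-DQ8/DR4-DQ8: 3.0
DR4-DQ8/X: 2.0
DR3/X: 1.8
X/X: 0.0
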