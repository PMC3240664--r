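# Molecularly mapped large-band control intervals, FlyBase release 5.18
# coordinates (0-based half-open on disk, BED-style start).
# NOTE: the source prints the 10A1-2 start as 108000000 (one digit too many,
# inconsistent with its end and with the chrX arm length); resolved here to
# 10800000 (10.8 Mb).
band	chrom	start	end
10A1-2	chrX	10800000	10980000
75C1	chr3L	18170000	18370000
75C2	chr3L	18450000	18610000
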