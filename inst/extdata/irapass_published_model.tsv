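event_id	coefficient
AIM2|chr1|159062567	0.785057366
BAX|chr19|48960961	0.660980225
COL27A1|chr9|114310700	-0.564149737
CTTN|chr11|70422660	-0.060074512
ERH|chr14|69380489	-0.037628233
GTF3C2-AS1|chr2|27337588	-1.267010808
NASP|chr1|45618212	0.819018066
RPL13|chr16|89563035	0.974817872
TAF15|chr17|35847057	-0.624692976
TMEM63A|chr1|225841036	-0.279070169
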