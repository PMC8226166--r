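label	annotation	charge
P0M0_ala	ARTKQTARKSTG-NME	5
P0M0_ace	ACE-RTKQTARKSTG-NME	4
P1M2	ART[ph]K[me3]QTAR[me2]KSTG-NME	3
P2M4	ACE-R[me2]T[ph]K[me3]QTAR[me2]K[me3]S[ph]TG-NME	0
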