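# RAFF2 P-packet presets for stretching factors TL 0.6-2.0.
# peak_hz: nominal peak amplitude of the pulse; packet_ms / refocus_ms:
# length of the four-element P-packet and of one refocusing element.
# Durations scale as TL times the TL1.0 packet (2.25 ms at 625 Hz).
# Note: the TL0.6 preset uses 608 Hz peak amplitude with durations kept on
# the 625 Hz time base, and the TL2.0 packet length is listed as 4.55 ms
# (exact 2x scaling gives 4.53 ms); both retained verbatim from the preset
# table this file mirrors.
TL	peak_hz	packet_ms	refocus_ms
0.6	608	1.35	0.34
0.8	625	1.8	0.45
1.0	625	2.25	0.57
1.2	625	2.7	0.68
1.4	625	3.15	0.79
1.6	625	3.6	0.9
1.8	625	4.05	1.01
2.0	625	4.55	1.14
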