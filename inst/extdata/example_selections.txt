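Selection	View	Channel	Begin Time (s)	End Time (s)	Caller
1	Waveform 1	1	2.104	2.451	Pobla
1	Spectrogram 1	1	2.104	2.451	Pobla
2	Waveform 1	1	3.002	3.391	Pobla
3	Waveform 1	1	5.120	5.433	unknown
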