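# Thirty average daily wind speeds (km/h), November 2007, Elanora
# Heights, Sydney, Australia.  Sum = 125.1, mean = 4.17 exactly; the
# loader validates this to guard against transcription drift.
2.7
3.2
2.1
4.8
7.6
4.7
4.2
4.0
2.9
2.9
4.6
4.8
4.3
4.6
3.7
2.4
4.9
4.0
7.7
10.0
5.2
2.6
4.2
3.6
2.5
3.3
3.1
3.7
2.8
4.0
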