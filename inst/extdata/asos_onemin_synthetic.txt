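13904KVKS 200301150000 10.5 0.059 N 33 5 28.0 20.5
13904KVKS 200301150001 10.5 0.059 N 33 5 27.5 20.4
13904KVKS 200301150002 10.4 0.060 N 34 6 27.0 20.3
13904KVKS 200301150003 10.4 0.060 N 34 6 26.6 20.1
13904KVKS 200301150004 10.3 0.061 N 35 6 26.1 20.0
13904KVKS 200301150005 10.3 0.061 N 35 7 32.0 20.0
13904KVKS 200301150006 10.2 0.062 N 36 7 41.0 19.9
13904KVKS 200301150007 10.2 0.062 N 36 7 50.0 19.8
13904KVKS 200301150008 10.1 0.063 N 37 8 59.0 19.7
13904KVKS 200301150009 10.1 0.063 N 37 8 68.0 19.6
13904KVKS 200301150010 M M
13904KVKS no timestamp on this line 28.4 19.5
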