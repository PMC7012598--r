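{"config":{"switch_survey":{"margin":1,"oops":true}},"seed":1,"package_version":"0.1.0","timestamp":"2026-09-24T12:38:45+0000","failed":{"switch_survey":"schema error in 'switch_survey': unknown key(s): oops"}}
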