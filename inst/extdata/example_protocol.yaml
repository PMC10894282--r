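# Example reduced-rate protocol for quick demonstrations. The default
# acquisition protocol (6000 Hz, 20-450 Hz band, 7 channels, 10 movements,
# 2 trials x 5 cycles of 4 s relaxation + 3 s contraction) is what
# protocol_config() returns with no arguments; this file lowers the rate and
# band so a full session generates in seconds.
sampling_rate: 500
band: [20, 200]
f_max: 240
n_channels_unaffected: 7
n_channels_affected: 7
movements: [IF, KP, PP, IP, CW, CR, TP, WE, WF, WR]
relax_duration: 4
contract_duration: 3
cycles_per_trial: 5
trials: 2
adc_range: 11
trim_fraction: 0.15
bin_width: 0.4
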