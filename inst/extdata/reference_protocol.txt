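# Reference question protocol: lead-in rest then five alternating
# task/rest cycles at the 300 ms frame interval (330 s per question).
lead_in_rest_s=30
n_cycles=5
task_s=30
cycle_rest_s=30
frame_interval_s=0.3
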