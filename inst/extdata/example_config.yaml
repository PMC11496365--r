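# Typical busy single-radiologist clinic with a CADt operating at the
# average cleared-device performance (Se 95%, Sp 89%).
f: 0
prevalence: 0.1
se: 0.95
sp: 0.89
n_rad: 1
read_time_interrupting_min: 5
read_time_diseased_min: 10
read_time_nondiseased_min: 10
rho: 0.8
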