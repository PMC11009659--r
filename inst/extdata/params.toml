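# calibrated parameter sets
[wt]
n_tot = 1900
k1_rest = 0.69999999999999996
k1_max = 2.7999999999999998
k1_half = 300
b1 = 0.091840385683261722
k2_rest = 0.016706312900274474
k2_max = 0.23738394677843466
k2_half = 5
b2 = 0.02
sk = 0.0064999999999999997
kf_max = 0.058774028078748271
kf_half = 300
bf = 2.5
p_fusion = 0.47999999999999998
s_ap = 0.14650344037309193
k_untight = 6.7740172398887859
ts_basal = 0.0078353658536585366
ts_gamma_max = 20000
ts_hill_n = 4
ts_kd = 30000
fs_basal = 0
fs_gamma_max = 2.7200000000000002
fs_hill_n = 3.3999999999999999
fs_kd = 107
ca_rest = 50
ca_a_fast = 120
ca_a_slow = 30.076188301134088
ca_tau_fast = 0.040000000000000001
ca_tau_slow = 0.32000000000000001

[ko]
n_tot = 1900
k1_rest = 0.69999999999999996
k1_max = 2.7999999999999998
k1_half = 300
b1 = 0.19216094774415546
k2_rest = 0.013317307692307693
k2_max = 0.12565006143604202
k2_half = 5
b2 = 0.02
sk = 0.065000000000000002
kf_max = 2.4337703549667968
kf_half = 300
bf = 2.5
p_fusion = 0.20999999999999999
s_ap = 0.053217565531508103
k_untight = 6.7740172398887859
ts_basal = 0.0044699646643109534
ts_gamma_max = 20000
ts_hill_n = 4
ts_kd = 30000
fs_basal = 0
fs_gamma_max = 2.7200000000000002
fs_hill_n = 3.3999999999999999
fs_kd = 107
ca_rest = 50
ca_a_fast = 120
ca_a_slow = 30.076188301134088
ca_tau_fast = 0.040000000000000001
ca_tau_slow = 0.32000000000000001

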