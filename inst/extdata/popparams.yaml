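# Final population pharmacokinetic parameter sets.
# Keys match the arguments of pop_dabohd() / pop_tra().
dabohd:
  cl_f: 19.3        # L/h, DAB apparent clearance (typical man, age 61.2)
  v2_f: 39.1        # L
  ka: 1.8           # 1/h, fixed
  q_f: 3.40         # L/h
  v4_f: 18.7        # L
  clm_f: 23.2       # L/h, OHD apparent clearance
  v3_f: 5.11        # L
  qm_f: 7.21        # L/h
  v5_f: 27.1        # L
  tlag: 0.499       # h
  theta_age_cl: -0.536
  theta_age_clm: -0.589
  theta_sex_cl: 0.832
  m_age: 61.2       # years, centering constant
  iiv_cl: 0.160
  iiv_v2: 0.508
  iiv_clm: 0.240
  iiv_v3: 0.475
  iov_cl: 0.174
  ruv_dab: 0.487
  ruv_ohd: 0.531
  ruv_corr: 0.870
  mw_dab: 519.56    # g/mol
  mw_ohd: 535.56    # g/mol
tra:
  cl_f: 5.83        # L/h
  v2_f: 61.9        # L
  ka: 0.913         # 1/h
  q_f: 64.9         # L/h
  v3_f: 417.0       # L
  tlag: 0.709       # h
  iiv_cl: 0.296
  iiv_q: 0.802
  ruv_add: 4.14     # ng/mL
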