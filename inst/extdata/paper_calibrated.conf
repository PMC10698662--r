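# Paper-calibrated simulation world: every value annotated with the cohort
# statistic it reproduces. Used as the default by `nightfit simulate`.
simulate = true
min_days = 7                     # inclusion: >= 7 matched valid nights
cap_days = 14                    # first 14 device days per participant
ampm_hours = 9                   # exclusion threshold for diary-device gaps
coverage_thresholds = 30,60      # +/-30 and +/-60 min coverage

sim_n_participants = 543         # analyzed cohort size
sim_nights_per_participant = 14  # two-week wear/diary request
sim_fitbit_onset_mean_clock = 00:19:42   # mean device sleep onset
sim_onset_sd_between = 55        # onset marginal SD ~70 min, split
sim_onset_sd_within = 43         #   between/within participants
sim_fitbit_tst_mean = 428        # mean device TST 7:07:58
sim_tst_sd_between = 40          # TST marginal SD ~53 min, split
sim_tst_sd_within = 35
sim_waso_mean = 58               # device WASO 58 (SD 24) min
sim_waso_sd = 24
sim_report_onset_bias_mean = 8.65    # diary onset reported 8:39 late
sim_report_onset_bias_sd = 25        # diff SD 58.1/1.96 ~ 29.6, split
sim_report_offset_bias_mean = -5.65  # diary offset reported ~5:38 early
sim_report_offset_bias_sd = 25
sim_report_night_noise_sd = 15
sim_report_bias_good = 19.2      # AST over-report on good-rated nights
sim_report_bias_poor = -2.5      # near-zero AST bias on poor-rated nights
sim_ast_bias_sd_between = 30     # AST diff SD 87/1.96 ~ 44.4, split
sim_ast_night_noise_sd = 35
sim_heap_prob_30 = 0.49          # diary AST on :00/:30 grid 57.6 percent
sim_qos_good_prob = 0.70         # 4380 of 6276 nights rated good
sim_qos_corr = 0.6               # latent trait linking PSQI and nightly QoS
sim_psqi_good_prob = 0.60        # 318 of 533 scored <= 5
sim_psqi_missing_rate = 0.018    # 10 of 543 unclassified
sim_ampm_error_rate = 0.01
sim_order_error_rate = 0.01
sim_missing_chat_rate = 0.15     # ~11.6 matched nights per participant
sim_missing_fitbit_rate = 0.05
sim_rng_seed = 20201010
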