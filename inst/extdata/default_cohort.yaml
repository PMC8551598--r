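# Default synthetic cohort configuration.
#
# These values are SYNTHETIC defaults chosen so that the generator emulates
# the qualitative structure the analysis assumes: three planted behavioural
# profiles (C1 elevated on aggression / hyperactivity-impulsivity / peer
# relations; C2 on inattention / executive function; C3 on learning problems)
# plus a comparison group near the population T-score mean of 50, and regional
# time series with intrinsic-connectivity-network block covariance carrying a
# planted group-specific connectivity effect. They are generator parameters,
# not estimates from any empirical cohort.
profiles:
  scale_names: [Inattention, Hyperactivity/Impulsivity, Learning Problems,
                Executive Function, Aggression, Peer Relations]
  groups: [comparison, C1, C2, C3]
  means:
    comparison: [50, 50, 50, 50, 50, 50]
    C1:         [62, 72, 60, 62, 75, 70]
    C2:         [72, 68, 65, 72, 55, 58]
    C3:         [60, 52, 74, 62, 50, 64]
behaviour_noise_sd: 5
tscore_range: [10, 90]
n_regions: 100
n_timepoints: 266
region_var: 1.0
within_icn_cor: 0.30
between_icn_cor: 0.05
group_effects:
  - pair: [limbic, dorsal attention]
    delta: 0.15
    groups: [C2]
  - pair: [fronto-parietal, default mode]
    delta: -0.04
    groups: [C1]
covariate_model:
  age_range: [5, 15]
  p_male: 0.65
  fd_meanlog: -1.90    # lognormal FD trace, mm per volume (median ~0.15 mm)
  fd_sdlog: 0.45
  spike_prob: 0.03
  spike_range: [0.55, 1.5]
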