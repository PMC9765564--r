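# Default generative profiles for strains and media.
#
# Speeds are swimming speeds in water (1 cP), micrometres per second.
# Switch rates are continuous-time Markov rates (1/s).
# Division rates are 1/h; p_motile_daughter is per-environment.
# agar_mode_speed / agar_rot_diffusion describe swimming inside the agar
# meshwork, where confinement-driven stator recruitment changes the
# phenotype (most dramatically for dmotAB, which is barely motile in
# fluids but swims nearly like the wild type in agar).
strains:
  WT:
    mode_speed: {push: 35.0, pull: 33.0, wrapped: 22.0}
    agar_mode_speed: {push: 28.0, pull: 26.0, wrapped: 19.0}
    switch_rate: {push_to_cw: 0.675, cw_to_push: 0.825,
                  run_to_stop: 0.25, stop_to_run: 6.0}
    ccw_bias: 0.55
    wrapped_propensity_params: {shape: logistic, midpoint: 2.0,
                                steepness: 1.8, max: 0.97}
    rot_diffusion: 0.1
    division_rate: 0.5
    p_motile_daughter: {"bulk": 1.0, "ficoll": 1.0,
                        "agar0.25": 0.90, "agar0.3": 0.85}
  dmotAB:
    # barely motile in fluids: low speeds, short erratic runs;
    # recovers near-wild-type swimming inside the agar meshwork
    mode_speed: {push: 7.0, pull: 6.0, wrapped: 4.5}
    agar_mode_speed: {push: 22.0, pull: 20.5, wrapped: 15.0}
    switch_rate: {push_to_cw: 0.375, cw_to_push: 1.125,
                  run_to_stop: 0.25, stop_to_run: 6.0}
    ccw_bias: 0.75
    wrapped_propensity_params: {shape: peaked, midpoint: 10.0,
                                steepness: 2.0, max: 0.35}
    rot_diffusion: 2.5
    agar_rot_diffusion: 0.1
    division_rate: 0.5
    p_motile_daughter: {"bulk": 1.0, "ficoll": 1.0,
                        "agar0.25": 0.88, "agar0.3": 0.82}
  dmotCD:
    # indistinguishable from WT in fluids; sessile clusters in agar
    mode_speed: {push: 35.5, pull: 33.0, wrapped: 22.0}
    agar_mode_speed: {push: 31.0, pull: 29.0, wrapped: 21.0}
    switch_rate: {push_to_cw: 0.675, cw_to_push: 0.825,
                  run_to_stop: 0.25, stop_to_run: 6.0}
    ccw_bias: 0.55
    wrapped_propensity_params: {shape: logistic, midpoint: 2.0,
                                steepness: 1.8, max: 0.95}
    rot_diffusion: 0.1
    division_rate: 0.5
    p_motile_daughter: {"bulk": 1.0, "ficoll": 1.0,
                        "agar0.25": 0.35, "agar0.3": 0.12}
  dmotABCD:
    mode_speed: {push: 0.0, pull: 0.0, wrapped: 0.0}
    switch_rate: {push_to_cw: 0.675, cw_to_push: 0.825,
                  run_to_stop: 0.25, stop_to_run: 6.0}
    ccw_bias: 0.55
    wrapped_propensity_params: {shape: logistic, midpoint: 2.0,
                                steepness: 1.8, max: 0.0}
    rot_diffusion: 0.1
    division_rate: 0.5
    p_motile_daughter: {"bulk": 0.0, "ficoll": 0.0,
                        "agar0.25": 0.0, "agar0.3": 0.0}
environments:
  bulk:
    kind: bulk
    ficoll_pct: 0.0
    viscosity: 1.0
    trap_rate: 0.0
    trap_duration_mean: 0.0
  ficoll10:
    kind: bulk
    ficoll_pct: 10.0
    viscosity: 5.0
    trap_rate: 0.0
    trap_duration_mean: 0.0
  ficoll15:
    kind: bulk
    ficoll_pct: 15.0
    viscosity: 10.0
    trap_rate: 0.0
    trap_duration_mean: 0.0
  ficoll20:
    kind: bulk
    ficoll_pct: 20.0
    viscosity: 18.0
    trap_rate: 0.0
    trap_duration_mean: 0.0
  agar0.25:
    kind: agar
    agar_pct: 0.25
    viscosity: 1.0
    pore_range: [740.0, 4800.0]   # nm
    trap_rate: 0.08               # encounters per um of run path at 1 um pore
    trap_duration_mean: 1.0       # s
    load_equiv: 8.0               # cP-equivalent load for mode propensities
  agar0.3:
    kind: agar
    agar_pct: 0.30
    viscosity: 1.0
    pore_range: [500.0, 3200.0]
    trap_rate: 0.08
    trap_duration_mean: 1.2
    load_equiv: 10.0
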