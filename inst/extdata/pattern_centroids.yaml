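# Trophic-pattern centroid table: per-pattern means and SDs for each
# metric-vector field, used by the z-space nearest-centroid stage of
# classify_pattern(). Order defines the tie-break priority.
#
# entropy_dits, density_pct and the four counts are the published per-subtype
# cohort statistics. necrosis_fraction and perivascular_fraction are not
# published; they are reconstruction constants matched to the packaged
# synthetic generator (necrosis: moments of the profile's uniform
# necrosis-fraction range; perivascular: empirical cohort moments of the
# calibrated generator at the default 100 um radius).
centroids:
  - pattern: proliferative_vascular
    subtype: micropapillary
    entropy_dits: {mean: 3.59, sd: 0.99}
    density_pct: {mean: 0.05, sd: 0.02}
    n_small_center: {mean: 30.60, sd: 26.44}
    n_small_periphery: {mean: 128.00, sd: 115.10}
    n_large_center: {mean: 11.93, sd: 10.59}
    n_large_periphery: {mean: 43.40, sd: 38.11}
    necrosis_fraction: {mean: 0.025, sd: 0.0144}
    perivascular_fraction: {mean: 0.010, sd: 0.010}
  - pattern: hypoxic
    subtype: solid
    entropy_dits: {mean: 3.28, sd: 1.68}
    density_pct: {mean: 0.01, sd: 0.01}
    n_small_center: {mean: 10.03, sd: 14.48}
    n_small_periphery: {mean: 42.59, sd: 63.15}
    n_large_center: {mean: 4.44, sd: 6.45}
    n_large_periphery: {mean: 14.26, sd: 20.64}
    necrosis_fraction: {mean: 0.15, sd: 0.0866}
    perivascular_fraction: {mean: 0.095, sd: 0.020}
  - pattern: proliferative
    subtype: acinar
    entropy_dits: {mean: 2.30, sd: 1.80}
    density_pct: {mean: 0.03, sd: 0.02}
    n_small_center: {mean: 19.71, sd: 23.87}
    n_small_periphery: {mean: 75.04, sd: 88.18}
    n_large_center: {mean: 7.27, sd: 7.35}
    n_large_periphery: {mean: 26.28, sd: 31.37}
    necrosis_fraction: {mean: 0.025, sd: 0.0144}
    perivascular_fraction: {mean: 0.237, sd: 0.040}
  - pattern: vascular
    subtype: papillary
    entropy_dits: {mean: 3.22, sd: 1.88}
    density_pct: {mean: 0.02, sd: 0.01}
    n_small_center: {mean: 13.30, sd: 7.14}
    n_small_periphery: {mean: 53.308, sd: 18.781}
    n_large_center: {mean: 4.84, sd: 2.37}
    n_large_periphery: {mean: 18.69, sd: 7.02}
    necrosis_fraction: {mean: 0.025, sd: 0.0144}
    perivascular_fraction: {mean: 0.089, sd: 0.025}
  - pattern: inactive
    subtype: lepidic
    entropy_dits: {mean: 1.19, sd: 1.51}
    density_pct: {mean: 0.03, sd: 0.02}
    n_small_center: {mean: 9.04, sd: 2.08}
    n_small_periphery: {mean: 42.04, sd: 52.54}
    n_large_center: {mean: 9.22, sd: 5.01}
    n_large_periphery: {mean: 14.42, sd: 16.74}
    necrosis_fraction: {mean: 0.025, sd: 0.0144}
    perivascular_fraction: {mean: 0.005, sd: 0.020}
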