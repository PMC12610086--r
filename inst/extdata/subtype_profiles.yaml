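# Default generator profiles, one per histologic subtype of lung
# adenocarcinoma.
#
# entropy_*, density_* and the four compartment-by-caliber vessel count
# targets are the published per-subtype cohort statistics (mean/SD).
# The remaining fields are generator calibration constants:
#   - clustering_weight: bisection-calibrated (calibrate_clustering_weight)
#     so the mean grid entropy at the default 150 um cell matches the
#     entropy target within 0.1 dit;
#   - n_mitoses_mean / n_cluster_seeds / cluster_sd_um: point-process shape
#     chosen so the entropy target lies inside the reachable [w=1, w=0]
#     entropy bracket;
#   - small/large_area_range: log-uniform vessel mask area ranges (um^2);
#     the large-vessel upper bound is solved per subtype so that
#     E[counts] x E[area] / tumor area reproduces the density target.
profiles:
  - subtype: micropapillary
    entropy_mean: 3.59
    entropy_sd: 0.99
    density_mean: 0.05
    density_sd: 0.02
    n_small_center_mean: 30.60
    n_small_center_sd: 26.44
    n_small_periphery_mean: 128.00
    n_small_periphery_sd: 115.10
    n_large_center_mean: 11.93
    n_large_center_sd: 10.59
    n_large_periphery_mean: 43.40
    n_large_periphery_sd: 38.11
    necrosis_fraction_range: [0.0, 0.05]
    clustering_weight: 0.0
    n_mitoses_mean: 8000
    n_cluster_seeds: 10
    cluster_sd_um: 150
    small_area_range: [20, 300]
    large_area_range: [300, 34100]
  - subtype: solid
    entropy_mean: 3.28
    entropy_sd: 1.68
    density_mean: 0.01
    density_sd: 0.01
    n_small_center_mean: 10.03
    n_small_center_sd: 14.48
    n_small_periphery_mean: 42.59
    n_small_periphery_sd: 63.15
    n_large_center_mean: 4.44
    n_large_center_sd: 6.45
    n_large_periphery_mean: 14.26
    n_large_periphery_sd: 20.64
    necrosis_fraction_range: [0.10, 0.40]
    clustering_weight: 0.3125
    n_mitoses_mean: 6000
    n_cluster_seeds: 8
    cluster_sd_um: 150
    small_area_range: [20, 300]
    large_area_range: [300, 14950]
  - subtype: papillary
    entropy_mean: 3.22
    entropy_sd: 1.88
    density_mean: 0.02
    density_sd: 0.01
    n_small_center_mean: 13.30
    n_small_center_sd: 7.14
    n_small_periphery_mean: 53.308
    n_small_periphery_sd: 18.781
    n_large_center_mean: 4.84
    n_large_center_sd: 2.37
    n_large_periphery_mean: 18.69
    n_large_periphery_sd: 7.02
    necrosis_fraction_range: [0.0, 0.05]
    clustering_weight: 0.3125
    n_mitoses_mean: 5500
    n_cluster_seeds: 6
    cluster_sd_um: 150
    small_area_range: [20, 300]
    large_area_range: [300, 33370]
  - subtype: lepidic
    entropy_mean: 1.19
    entropy_sd: 1.51
    density_mean: 0.03
    density_sd: 0.02
    n_small_center_mean: 9.04
    n_small_center_sd: 2.08
    n_small_periphery_mean: 42.04
    n_small_periphery_sd: 52.54
    n_large_center_mean: 9.22
    n_large_center_sd: 5.01
    n_large_periphery_mean: 14.42
    n_large_periphery_sd: 16.74
    necrosis_fraction_range: [0.0, 0.05]
    clustering_weight: 0.9375
    n_mitoses_mean: 60
    n_cluster_seeds: 1
    cluster_sd_um: 150
    cluster_seed: uniform
    small_area_range: [20, 300]
    large_area_range: [300, 25400]
  - subtype: acinar
    entropy_mean: 2.30
    entropy_sd: 1.80
    density_mean: 0.03
    density_sd: 0.02
    n_small_center_mean: 19.71
    n_small_center_sd: 23.87
    n_small_periphery_mean: 75.04
    n_small_periphery_sd: 88.18
    n_large_center_mean: 7.27
    n_large_center_sd: 7.35
    n_large_periphery_mean: 26.28
    n_large_periphery_sd: 31.37
    necrosis_fraction_range: [0.0, 0.05]
    clustering_weight: 0.8125
    n_mitoses_mean: 3000
    n_cluster_seeds: 6
    cluster_sd_um: 150
    small_area_range: [20, 300]
    large_area_range: [300, 33330]
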