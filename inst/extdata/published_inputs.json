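{
  "comment": "Published input values for the fixture-based reproduction run. All downstream numbers are recomputed from these by run_paper_fixtures().",
  "dimer_pct": [11.23, 7.60, 5.19, 6.47],
  "cell_cycle_fractions": {"G1": 0.102, "S": 0.739, "G2": 0.159},
  "sites_haploid_counts": [68077, 74374],
  "genome_size_Mb": 2716,
  "bound_fractions": [0.489, 0.493],
  "engaged_fraction": 0.398,
  "method_estimates": {
    "mESC_CTCF": [215200, 219200],
    "U2OS_CTCF": [104900, 114600],
    "mESC_Rad21": [86900, 131800]
  },
  "expected": {
    "occupancy": 0.499,
    "density_molecules_per_Mb": 5.34,
    "density_pairs_per_Mb": 2.67,
    "dimer_mean_pct": 7.62,
    "dimer_std_pct": 2.6,
    "bound_fraction_mean": 0.491,
    "sites_haploid": 71200,
    "sites_total": 213600,
    "final_mESC_CTCF": 217200,
    "final_U2OS_CTCF": 109800,
    "final_mESC_Rad21": 109400,
    "genome_copies": 3
  }
}
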