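# Published component costs (euro millions, 2008 prices) used as model
# inputs in the arithmetic-identity tests: drug, physician, CVD, T2D for
# the hypertensive population with and without MetS, per country and year.

printed_costs <- function() {
  tibble::tribble(
    ~country, ~year, ~slice,     ~drug, ~physician, ~cvd, ~t2d, ~total,
    "germany", 2008, "mets",       628,       1952, 5265, 16582, 24427,
    "germany", 2008, "non_mets",   407,       1264, 1703,  1967,  5341,
    "spain",   2008, "mets",       116,        126,  699,   968,  1909,
    "spain",   2008, "non_mets",   397,        432, 1256,   597,  2682,
    "italy",   2008, "mets",       258,        330,  817,  3472,  4877,
    "italy",   2008, "non_mets",   958,       1222, 1599,  2178,  5957,
    "germany", 2020, "mets",       901,       2820, 8026, 27208, 38955,
    "germany", 2020, "non_mets",   270,        817, 1124,  1600,  3811,
    "spain",   2020, "mets",       301,        333, 1952,  2743,  5329,
    "spain",   2020, "non_mets",   384,        412, 1240,   816,  2852,
    "italy",   2020, "mets",       629,        813, 2117,  8964, 12523,
    "italy",   2020, "non_mets",   877,       1109, 1500,  2701,  6187
  )
}

# Published 2020 all-hypertension totals and their 3%-over-12-years
# discounted counterparts (euro millions).
printed_discounting <- function() {
  tibble::tibble(
    country = c("germany", "spain", "italy"),
    total_2020 = c(42769, 8180, 18710),
    discounted = c(29997, 5737, 13123)
  )
}

# Published one-at-a-time sensitivity cells for the three unit-cost
# families (euro millions): total annual cost with ("mets") and without
# ("non_mets") MetS under +/-20% of one unit-cost family.
printed_sensitivity_cells <- function() {
  tibble::tribble(
    ~country,  ~target, ~factor, ~slice,     ~printed,
    "germany", "drug",     1.2, "mets",      24553,
    "germany", "drug",     1.2, "non_mets",   5423,
    "germany", "drug",     0.8, "mets",      24247,
    "germany", "drug",     0.8, "non_mets",   5224,
    "germany", "cvd",      1.2, "mets",      25481,
    "germany", "cvd",      1.2, "non_mets",   5682,
    "germany", "cvd",      0.8, "mets",      23373,
    "germany", "cvd",      0.8, "non_mets",   5000,
    "germany", "t2d",      1.2, "mets",      27743,
    "germany", "t2d",      1.2, "non_mets",   5735,
    "germany", "t2d",      0.8, "mets",      21112,
    "germany", "t2d",      0.8, "non_mets",   4948,
    "spain",   "drug",     1.2, "mets",       1928,
    "spain",   "drug",     1.2, "non_mets",   4329,
    "spain",   "drug",     0.8, "mets",       1886,
    "spain",   "drug",     0.8, "non_mets",   2603,
    "spain",   "cvd",      1.2, "mets",       2049,
    "spain",   "cvd",      1.2, "non_mets",   2934,
    "spain",   "cvd",      0.8, "mets",       1769,
    "spain",   "cvd",      0.8, "non_mets",   2431,
    "spain",   "t2d",      1.2, "mets",       2102,
    "spain",   "t2d",      1.2, "non_mets",   2803,
    "spain",   "t2d",      0.8, "mets",       1715,
    "spain",   "t2d",      0.8, "non_mets",   2564,
    "italy",   "drug",     1.2, "mets",       4929,
    "italy",   "drug",     1.2, "non_mets",   6147,
    "italy",   "drug",     0.8, "mets",       4825,
    "italy",   "drug",     0.8, "non_mets",   5762,
    "italy",   "cvd",      1.2, "mets",       5041,
    "italy",   "cvd",      1.2, "non_mets",   6276,
    "italy",   "cvd",      0.8, "mets",       4714,
    "italy",   "cvd",      0.8, "non_mets",   5637,
    "italy",   "t2d",      1.2, "mets",       5573,
    "italy",   "t2d",      1.2, "non_mets",   6392,
    "italy",   "t2d",      0.8, "mets",       4183,
    "italy",   "t2d",      0.8, "non_mets",   5521
  )
}
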