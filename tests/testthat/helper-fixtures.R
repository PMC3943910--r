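# Shared fixtures and independent oracles for the test suite.

# Brute-force Mann-Whitney pair counting: the independent oracle for the
# C-statistic (wins + half-ties over all disease x control pairs).
cstat_brute <- function(d, c) {
  wins <- 0
  for (x in d) for (y in c)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(d) * length(c))
}

# Build a gradient_matrix directly from a numeric matrix + labels,
# bypassing chromatogram I/O.
make_gm <- function(X, labels, aggregate = "sum") {
  structure(
    list(gradients = X, labels = labels,
         subject_ids = sprintf("S%02d", seq_len(nrow(X))),
         aggregate = aggregate),
    class = "gradient_matrix")
}

# Paired-record fixture from raw response vectors.
make_record <- function(id, label, breath, air, scan_rate = 3013) {
  subject_record(id, label,
                 breath = chromatogram(breath, "breath", id, scan_rate),
                 air = chromatogram(air, "air", id, scan_rate))
}

# Half-up rounding, written out independently of the package internals.
round_half_up_oracle <- function(x) floor(x + 0.5)

# Exact permutation distribution of the folded AUC for nd + nc untied
# values: enumerate every class assignment.
exact_folded_null <- function(values, nd) {
  n <- length(values)
  splits <- utils::combn(n, nd)
  apply(splits, 2, function(rows)
    max(c_statistic(values[rows], values[-rows]),
        1 - c_statistic(values[rows], values[-rows])))
}
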