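# Shared helpers: fixture builders and small independent oracles.

# Write a tidy concentration CSV to a temp file and return its path.
write_fixture_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(rows, path)
  path
}

std_rows <- function(sample_id, system, medium, element, value_mg_kg) {
  tibble::tibble(sample_id = sample_id, system = system, medium = medium,
                 element = element, value_mg_kg = value_mg_kg)
}

# Two observations m +/- s/sqrt(2) have sample mean m and sample sd s exactly.
two_point_sample <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))

# Tucker congruence coefficient between two loading vectors.
congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best absolute congruence match of each target column among candidate
# columns, allowing sign flips and permutation.
match_congruence <- function(target, candidate) {
  apply(target, 2, function(t)
    max(apply(candidate, 2, function(c) abs(congruence(t, c)))))
}

# Published EDI table (ug/kg/day) used by reproduction tests.
published_edi <- function() {
  tibble::tribble(
    ~system, ~food, ~population, ~Cr, ~Ni, ~Cu, ~Zn, ~As, ~Cd, ~Hg, ~Pb,
    "RCS", "rice", "child", 0.65, 1.76, 29.95, 107.81, 0.38, 0.24, 0.10, 0.34,
    "RCS", "rice", "adult", 0.33, 0.88, 15.02, 54.06, 0.19, 0.12, 0.05, 0.17,
    "RCS", "crayfish", "child", 0.05, 0.02, 2.10, 9.41, 0.11, 0.00, 0.07, 0.03,
    "RCS", "crayfish", "adult", 0.05, 0.02, 2.08, 9.33, 0.11, 0.00, 0.07, 0.03,
    "CRC", "rice", "child", 0.74, 0.93, 30.69, 105.24, 0.64, 0.22, 0.05, 0.36,
    "CRC", "rice", "adult", 0.37, 0.47, 15.39, 52.78, 0.32, 0.11, 0.02, 0.18
  )
}

# Published THQ/HI table; NA marks cells printed only as "<0.0001".
published_thq_hi <- function() {
  tibble::tribble(
    ~system, ~food, ~population, ~Cr, ~Ni, ~Cu, ~Zn, ~As, ~Cd, ~Hg, ~Pb, ~HI,
    "CRC", "rice", "adult", 0.0002, 0.023, 0.38, 0.17, 1.07, 0.11, 0.15, 0.052, 1.97,
    "CRC", "rice", "child", 0.0005, 0.046, 0.77, 0.35, 2.13, 0.22, 0.29, 0.10, 3.91,
    "RCS", "rice", "adult", 0.0002, 0.044, 0.37, 0.18, 0.63, 0.12, 0.29, 0.048, 1.70,
    "RCS", "rice", "child", 0.0004, 0.088, 0.75, 0.36, 1.26, 0.24, 0.59, 0.095, 3.38,
    "RCS", "crayfish", "adult", NA, 0.0009, 0.052, 0.031, 0.35, 0.001, 0.43, 0.0079, 0.87,
    "RCS", "crayfish", "child", NA, 0.0009, 0.053, 0.031, 0.36, 0.001, 0.43, 0.0080, 0.88
  )
}

# Published soil-to-grain transfer factors (3-decimal print precision).
published_tf <- function() {
  tibble::tribble(
    ~system, ~element, ~tf,
    "RCS", "As", 0.003, "RCS", "Cd", 0.066, "RCS", "Cr", 0.001,
    "RCS", "Cu", 0.062, "RCS", "Hg", 0.125, "RCS", "Ni", 0.004,
    "RCS", "Pb", 0.001, "RCS", "Zn", 0.098,
    "CRC", "As", 0.005, "CRC", "Cd", 0.059, "CRC", "Cr", 0.001,
    "CRC", "Cu", 0.065, "CRC", "Hg", 0.050, "CRC", "Ni", 0.002,
    "CRC", "Pb", 0.001, "CRC", "Zn", 0.101
  )
}

# A soil concentration table whose per-element sample mean and SD equal the
# published moments exactly (two samples per element).
moment_exact_soil <- function(system = "RCS") {
  mom <- dplyr::filter(study_soil_moments(), system == !!system)
  rows <- do.call(rbind, lapply(seq_len(nrow(mom)), function(i) {
    v <- two_point_sample(mom$mean[i], mom$sd[i])
    data.frame(sample_id = paste0("s", seq_along(v)), system = system,
               medium = "soil", element = mom$element[i], value = v)
  }))
  concentration_table(rows)
}
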