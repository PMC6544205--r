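# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by direct enumeration or per-row scanning, never via the
# package functions they check.

# Size of a minimum vertex cover, by subset enumeration (graphs <= ~12 nodes).
brute_min_vertex_cover <- function(id1, id2) {
  if (!length(id1)) return(0L)
  nodes <- sort(unique(c(id1, id2)))
  for (k in 0:length(nodes)) {
    for (s in utils::combn(nodes, k, simplify = FALSE)) {
      if (all(id1 %in% s | id2 %in% s)) return(k)
    }
  }
  length(nodes)
}

is_vertex_cover <- function(cover, id1, id2) {
  all(id1 %in% cover | id2 %in% cover)
}

# Per-individual scan: does any diagnosis cell of the row match the pattern?
brute_pattern_hits <- function(data, pattern, cols) {
  vapply(seq_len(nrow(data)), function(r) {
    vals <- unlist(lapply(cols, function(cl) as.character(data[[cl]][r])))
    any(!is.na(vals) & grepl(pattern, vals, perl = TRUE))
  }, NA)
}

# Random kinship graph over ids 1..n_nodes as character labels.
random_kinship_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  pool <- t(utils::combn(paste0("s", seq_len(n_nodes)), 2))
  take <- sample.int(nrow(pool), min(n_edges, nrow(pool)))
  tibble::tibble(id1 = pool[take, 1], id2 = pool[take, 2],
                 kinship = runif(length(take), -0.02, 0.45),
                 ibs0 = runif(length(take), 0, 0.01))
}

# A small assembled-dataset stand-in with diagnosis columns, built directly.
make_dx_dataset <- function(n, seed, codes = ukbkit::ukb_icd_codes("icd10")$code,
                            p_missing = 0.3) {
  set.seed(seed)
  draw <- function() ifelse(runif(n) < p_missing, NA,
                            sample(codes, n, replace = TRUE))
  tibble::tibble(
    eid = seq_len(n) + 1000L,
    sex_f31_0_0 = factor(sample(c("Female", "Male"), n, replace = TRUE)),
    body_mass_index_bmi_f21001_0_0 = rnorm(n, 27, 4),
    diagnoses_icd10_f41270_0_0 = draw(),
    diagnoses_icd10_f41270_0_1 = draw())
}
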