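# Shared fixtures, built once per test run (all generated in code, fixed seeds).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the study-scale scaled-mode gap-gene ensemble (n = 301, cv = 0.037, noise 0.05)
gap_ensemble <- function() fixture("gap", function() {
  generate_ensemble(make_gap_like_family(4),
                    draw_lengths(301, length_model(490, 0.037), seed = 11),
                    noise_sd = 0.05, seed = 12)
})

gap_binned <- function() fixture("gap_binned", function() bin_positions(gap_ensemble()))

# noiseless scaled-mode reference (ground-truth marker positions)
gap_noiseless <- function() fixture("gap0", function() {
  generate_ensemble(make_gap_like_family(4), rep(490, 3), times = rep(45, 3),
                    noise_sd = 0, seed = 1)
})

# ground-truth scaled boundary positions of the mean shapes
gap_truth <- function() fixture("gap_truth", function() {
  ens0 <- gap_noiseless()
  do.call(rbind, lapply(ens0$genes, function(g) {
    b <- detect_half_max_boundaries(ens0, g)
    agg <- aggregate(f ~ marker_id, b, mean)
    agg$gene <- g
    agg
  }))
})

pair_rule_ensemble <- function() fixture("pr", function() {
  fam <- make_pair_rule_family(7)
  generate_ensemble(fam, draw_lengths(108, length_model(490, 0.037), seed = 21),
                    noise_sd = 0.05, seed = 22)
})
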