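# Independent oracles used across test files.

# Exhaustive enumeration of one-dimensional transport plans. Residual
# masses are given in integer units (e.g. tenths); every matrix with the
# prescribed row sums (source residual) and column sums (target residual)
# is visited, and the range of upward- and downward-moved units recorded.
enumerate_transport_range <- function(units_in, units_atm) {
  stopifnot(length(units_in) == length(units_atm),
            sum(units_in) == sum(units_atm))
  B <- length(units_in)
  up_rng <- c(Inf, -Inf)
  down_rng <- c(Inf, -Inf)
  recurse <- function(i, a_rem, up, down) {
    if (i > B) {
      up_rng <<- c(min(up_rng[1], up), max(up_rng[2], up))
      down_rng <<- c(min(down_rng[1], down), max(down_rng[2], down))
      return(invisible())
    }
    distribute <- function(j, left, a_rem, up, down) {
      if (j > B) {
        if (left == 0) recurse(i + 1, a_rem, up, down)
        return(invisible())
      }
      for (x in 0:min(left, a_rem[j])) {
        a2 <- a_rem
        a2[j] <- a2[j] - x
        distribute(j + 1, left - x, a2,
                   up + if (j > i) x else 0,
                   down + if (j < i) x else 0)
      }
    }
    distribute(1, units_in[i], a_rem, up, down)
  }
  recurse(1, units_atm, 0, 0)
  list(up = up_rng, down = down_rng)
}

# random residual pair on a 0.1 grid with equal totals; disjoint support
# when disjoint = TRUE (as produced by histogram intersection)
random_residual_pair <- function(n_bins, total_units, disjoint = TRUE) {
  repeat {
    ui <- tabulate(sample.int(n_bins, total_units, replace = TRUE), n_bins)
    ua <- tabulate(sample.int(n_bins, total_units, replace = TRUE), n_bins)
    if (!disjoint) return(list(units_in = ui, units_atm = ua))
    overlap <- pmin(ui, ua)
    ui <- ui - overlap
    ua <- ua - overlap
    if (sum(ui) > 0) return(list(units_in = ui, units_atm = ua))
  }
}

# latent uptake vectors of a paired community, by condition
latent_uptakes <- function(com) {
  tr <- com$truth
  list(in_situ = tr$uptake_insitu[tr$condition == "in_situ"],
       atm = tr$uptake_atm[tr$condition == "atmospheric"])
}
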