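#' Discretize fluid and vasopressor doses onto a 5 x 5 action grid
#'
#' Each drug is binned into 5 dose levels: bin 0 holds exactly-zero doses and
#' bins 1-4 are quartiles of the observed non-zero doses (empirical quantiles
#' at probabilities 0.25/0.5/0.75; left-closed, right-open bins, last bin
#' right-closed). The composed action index is `a = 5 * fluid_bin + vaso_bin`
#' in `{0, ..., 24}`, so action 0 is "no fluids, no vasopressors". Each bin
#' carries a representative dose — the median observed dose in the bin, with
#' bin 0 mapping to exactly 0 — used to resolve a policy's recommended action
#' back to doses that hazard predicates can evaluate.
#'
#' With fewer than 4 distinct non-zero doses for a drug the bin count is
#' reduced for that drug (with a warning); the composed index space keeps the
#' factor 5 so indices remain stable.
#'
#' @param cohort a validated cohort.
#' @return a `sepsafe_action_grid`: per-drug bin edges and representative
#'   doses, plus `action_index`, the composed index for every cohort row.
#' @export
discretize_actions <- function(cohort) {
  validate_cohort(cohort)
  fluid <- .bin_drug(cohort$action_fluid, "fluid")
  vaso <- .bin_drug(cohort$action_vaso, "vasopressor")
  grid <- structure(
    list(fluid = fluid[c("edges", "representative", "n_bins")],
         vaso = vaso[c("edges", "representative", "n_bins")]),
    class = "sepsafe_action_grid"
  )
  grid$action_index <- compose_action(fluid$bin, vaso$bin)
  grid
}

.bin_drug <- function(dose, label) {
  nz <- dose[dose > 0]
  distinct <- unique(nz)
  if (length(distinct) == 0L) {
    warning("all ", label, " doses are zero; single-bin fallback")
    edges <- numeric(0)
  } else if (length(distinct) < 4L) {
    n_bins <- length(distinct)
    warning("only ", n_bins, " distinct non-zero ", label,
            " doses; reducing to ", n_bins, " non-zero bin(s)")
    probs <- seq_len(n_bins - 1L) / n_bins
    edges <- unique(unname(quantile(nz, probs = probs, type = 7)))
  } else {
    edges <- unique(unname(quantile(nz, probs = c(0.25, 0.5, 0.75), type = 7)))
    if (length(edges) < 3L) {
      warning("tied ", label, " quartiles; reducing bin count")
    }
  }
  bin <- ifelse(dose == 0, 0L, 1L + findInterval(dose, edges))
  representative <- c(0, vapply(
    seq_len(length(edges) + 1L),
    function(b) if (any(bin == b)) median(dose[bin == b]) else NA_real_,
    numeric(1)))
  list(edges = edges, representative = representative,
       n_bins = length(edges) + 2L, bin = as.integer(bin))
}

#' Compose / decompose the 25-action index
#'
#' @param fluid_bin,vaso_bin integer bins in 0-4.
#' @return `compose_action()` gives `5 * fluid_bin + vaso_bin`;
#'   `decompose_action()` returns a data frame of bins.
#' @export
compose_action <- function(fluid_bin, vaso_bin) {
  as.integer(5L * fluid_bin + vaso_bin)
}

#' @rdname compose_action
#' @param action composed action index in 0-24.
#' @export
decompose_action <- function(action) {
  data.frame(fluid_bin = action %/% 5L, vaso_bin = action %% 5L)
}

#' Resolve composed action indices to representative doses
#'
#' @param grid a `sepsafe_action_grid`.
#' @param action integer vector of composed indices in 0-24.
#' @return data frame with `fluid` (mL/step) and `vaso` (ug/kg/min)
#'   representative doses; bin 0 resolves to exactly 0 for either drug.
#' @export
resolve_action_doses <- function(grid, action) {
  stopifnot(inherits(grid, "sepsafe_action_grid"))
  if (any(action < 0 | action > 24)) {
    stop_sepsafe("action index out of range 0-24")
  }
  bins <- decompose_action(action)
  data.frame(
    fluid = grid$fluid$representative[bins$fluid_bin + 1L],
    vaso = grid$vaso$representative[bins$vaso_bin + 1L]
  )
}
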