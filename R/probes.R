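# Capture probe tiling. 120-mer probes are laid over each seed transcript
# with a denser tiling (19-nt step, ~6x interior depth) over the first third
# of the sequence -- where capture of the 5'UTR and promoter-proximal flank
# matters most -- and a sparser tiling (29-nt step, ~4x) over the remaining
# two thirds. Interior depth equals floor(probe_len / step).

#' Design tiling capture probes over seed transcripts
#'
#' Probe starts begin at 0 and advance by `step_first` while the start is
#' below the zone boundary `ceil(L/3)`, then by `step_rest` (no phase reset at
#' the boundary). Starts that would run past the 3' end are dropped and a
#' terminal probe at `L - probe_len` is appended when the last regular probe
#' does not reach the 3' end, so every base is covered. Seeds shorter than
#' `probe_len` are skipped with a warning; probes with too many ambiguous
#' bases are dropped with a warning (array manufacturability).
#'
#' @param seeds Sequence set (named character or DNAStringSet).
#' @param probe_len Probe length (nt).
#' @param step_first Tiling distance (nt) in the first third.
#' @param step_rest Tiling distance (nt) in the remaining two thirds.
#' @param max_n_frac Maximum tolerated fraction of `N` in a probe.
#' @return Data.frame `seed_id, start, zone, sequence` with 0-based starts,
#'   sorted by seed then start; `zone` is `first_third` or `rest`.
#' @examples
#' design_probes(c(s = strrep("ACGT", 30)))  # 120 nt -> single probe at 0
#' @export
design_probes <- function(seeds, probe_len = 120L, step_first = 19L,
                          step_rest = 29L, max_n_frac = 0.1) {
  if (probe_len <= 0L || step_first <= 0L || step_rest <= 0L) {
    stop("probe_len and tiling steps must be positive")
  }
  seeds <- as_seq_set(seeds, "seeds")
  rows <- list()
  for (sid in names(seeds)) {
    L <- nchar(seeds[[sid]])
    if (L < probe_len) {
      warning("seed ", sid, " shorter than probe length (", L, " < ",
              probe_len, "): skipped")
      next
    }
    starts <- probe_starts(L, probe_len, step_first, step_rest)
    boundary <- ceiling(L / 3)
    seqs <- substring(seeds[[sid]], starts + 1L, starts + probe_len)
    n_frac <- vapply(seqs, function(s)
      lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
      numeric(1))
    drop <- n_frac > max_n_frac
    if (any(drop)) {
      warning(sum(drop), " probe(s) on ", sid, " dropped (> ",
              round(100 * max_n_frac), "% N)")
    }
    keep <- !drop
    if (!any(keep)) next
    rows[[sid]] <- data.frame(
      seed_id = sid, start = starts[keep],
      zone = ifelse(starts[keep] < boundary, "first_third", "rest"),
      sequence = unname(seqs[keep]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(seed_id = character(0), start = integer(0),
                      zone = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The start rule, separated for direct testing: 0, +step_first while start <
# ceil(L/3), then +step_rest; drop starts past L - probe_len; append terminal
# start L - probe_len if uncovered; dedupe.
probe_starts <- function(L, probe_len, step_first, step_rest) {
  boundary <- ceiling(L / 3)
  starts <- integer(0)
  s <- 0L
  while (s < boundary) {
    starts <- c(starts, s)
    s <- s + step_first
  }
  s <- starts[length(starts)] + step_rest
  while (s + probe_len <= L) {
    starts <- c(starts, s)
    s <- s + step_rest
  }
  starts <- starts[starts + probe_len <= L]
  if (!length(starts) || max(starts) + probe_len < L) {
    starts <- c(starts, L - probe_len)
  }
  sort(unique(starts))
}

#' Per-base probe coverage profile and zone summary
#'
#' @param probes Data.frame from [design_probes()], restricted to one seed.
#' @param seed_len Seed length (nt).
#' @param probe_len Probe length used in the design.
#' @return List with `depth` (integer vector of length `seed_len`, per-base
#'   probe count) and `zones`, a data.frame with the modal interior depth per
#'   zone. Interior excludes a `probe_len`-sized ramp at each zone edge; zones
#'   too short to have an interior report `NA`.
#' @export
probe_coverage_profile <- function(probes, seed_len, probe_len = 120L) {
  stopifnot(seed_len >= 1L)
  if (length(unique(probes$seed_id)) > 1L) {
    stop("probe_coverage_profile expects probes of a single seed")
  }
  delta <- integer(seed_len + 1L)
  for (s in probes$start) {
    e <- min(s + probe_len, seed_len)
    delta[s + 1L] <- delta[s + 1L] + 1L
    delta[e + 1L] <- delta[e + 1L] - 1L
  }
  depth <- cumsum(delta[seq_len(seed_len)])
  boundary <- ceiling(seed_len / 3)
  interior <- function(lo, hi) {   # 0-based half-open zone span
    ilo <- lo + probe_len
    ihi <- hi - probe_len
    if (ihi <= ilo) return(NA_integer_)
    modal_int(depth[(ilo + 1L):ihi])
  }
  zones <- data.frame(
    zone = c("first_third", "rest"),
    zone_start = c(0L, boundary),
    zone_end = c(boundary, seed_len),
    modal_interior_depth = c(interior(0L, boundary),
                             interior(boundary, seed_len)),
    stringsAsFactors = FALSE)
  list(depth = as.integer(depth), zones = zones)
}
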