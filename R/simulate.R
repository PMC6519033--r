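#' Piecewise-constant recombination map
#'
#' A recombination map is a step function giving the per-bp population
#' recombination rate rho over `[0, length_bp)`: `breakpoints` are the
#' interior block boundaries (strictly increasing, 0-based) and `rates` has
#' one entry per block, i.e. `length(breakpoints) + 1` entries.
#'
#' @param length_bp total sequence length.
#' @param breakpoints interior breakpoints in `(0, length_bp)`.
#' @param rates per-bp rho per block, all `>= 0`.
#' @return An object of class `recomb_map`.
#' @examples
#' recomb_map(1000, 500, c(0.001, 0.01))
#' @export
recomb_map <- function(length_bp, breakpoints = numeric(0), rates) {
  breakpoints <- as.numeric(breakpoints)
  rates <- as.numeric(rates)
  if (length(breakpoints) &&
      (is.unsorted(breakpoints, strictly = TRUE) ||
       min(breakpoints) <= 0 || max(breakpoints) >= length_bp))
    stop("breakpoints must be strictly increasing and inside (0, length_bp)")
  if (length(rates) != length(breakpoints) + 1L)
    stop("need one rate per block: length(rates) == length(breakpoints) + 1")
  if (any(rates < 0)) stop("rates must be >= 0")
  structure(list(length_bp = as.numeric(length_bp),
                 breakpoints = breakpoints, rates = rates),
            class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("recomb_map: %g bp, %d block(s), rho in [%g, %g]\n",
              x$length_bp, length(x$rates), min(x$rates), max(x$rates)))
  invisible(x)
}

#' Number of constant blocks of a map
#' @param map a [recomb_map].
#' @export
n_blocks <- function(map) length(map$rates)

#' Evaluate a recombination map at positions
#'
#' @param map a [recomb_map].
#' @param pos bp positions in `[0, length_bp)`.
#' @return per-bp rho at each position.
#' @export
rho_at <- function(map, pos) {
  stopifnot(all(pos >= 0), all(pos < map$length_bp))
  map$rates[findInterval(pos, c(0, map$breakpoints))]
}

#' Build a hotspot recombination map
#'
#' Background rate everywhere except inside the given hotspots, where the
#' rate is `background_rho * intensity`. Hotspots are half-open
#' `[start, start + length)` intervals and must not overlap or touch.
#'
#' @param length_bp total sequence length.
#' @param background_rho per-bp background rho.
#' @param hotspots `data.frame` with columns `start`, `length`, `intensity`
#'   (fold-change over background, `> 1`). May have zero rows.
#' @return A [recomb_map]. A map with `h` interior hotspots has `2h + 1`
#'   blocks.
#' @examples
#' hotspot_map(30000, 0.001,
#'             data.frame(start = c(10000, 20000), length = 1000,
#'                        intensity = c(20, 35)))
#' @export
hotspot_map <- function(length_bp, background_rho, hotspots) {
  if (is.null(hotspots) || nrow(hotspots) == 0)
    return(recomb_map(length_bp, numeric(0), background_rho))
  stopifnot(all(c("start", "length", "intensity") %in% names(hotspots)))
  h <- hotspots[order(hotspots$start), , drop = FALSE]
  if (any(h$intensity <= 1)) stop("hotspot intensity must exceed 1")
  if (any(h$start < 0) || any(h$start + h$length > length_bp))
    stop("hotspot outside sequence")
  ends <- h$start + h$length
  if (nrow(h) > 1 && any(h$start[-1] < ends[-nrow(h)]))
    stop("overlapping hotspots")
  bks <- numeric(0); rates <- numeric(0)
  cur <- 0
  for (i in seq_len(nrow(h))) {
    if (h$start[i] > cur) {
      rates <- c(rates, background_rho)
      bks <- c(bks, h$start[i])
    }
    rates <- c(rates, background_rho * h$intensity[i])
    if (ends[i] < length_bp) bks <- c(bks, ends[i])
    cur <- ends[i]
  }
  if (cur < length_bp) rates <- c(rates, background_rho)
  recomb_map(length_bp, bks, rates)
}

#' Evenly spaced multi-hotspot map
#'
#' The evaluation design for long sequences: `n_hotspots` hotspots with
#' centres at `length_bp * i / (n_hotspots + 1)`, `i = 1..n_hotspots`.
#' Hotspot lengths alternate between 1 kb and 2 kb and intensities are
#' spread equidistantly over `intensity_range` from left to right.
#'
#' @param length_bp sequence length (default 1 Mb).
#' @param background_rho per-bp background rho.
#' @param n_hotspots number of hotspots (default 15).
#' @param intensity_range fold-change range, default `c(8, 40)`.
#' @param hotspot_lengths recycled vector of hotspot lengths in bp.
#' @return A [recomb_map] with `2 * n_hotspots + 1` blocks.
#' @export
natural_hotspot_map <- function(length_bp = 1e6, background_rho,
                                n_hotspots = 15,
                                intensity_range = c(8, 40),
                                hotspot_lengths = c(1000, 2000)) {
  centers <- length_bp * seq_len(n_hotspots) / (n_hotspots + 1)
  len <- rep_len(hotspot_lengths, n_hotspots)
  hotspot_map(length_bp, background_rho, data.frame(
    start = centers - len / 2, length = len,
    intensity = seq(intensity_range[1], intensity_range[2],
                    length.out = n_hotspots)))
}

#' Bottleneck-growth demography
#'
#' A three-epoch population-size history: looking back from the present,
#' the relative size eta(t) is 100 for `-0.5 < t <= 0`, 0.1 for
#' `-0.58 < t <= -0.5` and 1 for `t <= -0.58` — a bottleneck followed by
#' rapid growth. Time is in coalescent units of `2 * Ne` generations, with
#' the ancestral epoch (eta = 1) as the reference size defining rho and
#' theta.
#'
#' @return An object of class `demography_model` with fields
#'   `epoch_boundaries` (times of the size changes, negative, most recent
#'   first) and `relative_sizes` (one per epoch, present epoch first).
#' @export
bottleneck_growth_demography <- function() {
  structure(list(epoch_boundaries = c(-0.5, -0.58),
                 relative_sizes = c(100, 0.1, 1)),
            class = "demography_model")
}

#' Relative population size at a (negative) coalescent time
#' @param dem a `demography_model`.
#' @param t coalescent times, `t <= 0`.
#' @export
demography_eta <- function(dem, t) {
  stopifnot(all(t <= 0))
  # epoch i covers -t in [b_{i-1}, b_i): t = -0.5 already belongs to epoch 2
  idx <- findInterval(-t, c(0, -dem$epoch_boundaries))
  dem$relative_sizes[idx]
}

#' Factorial grid of constant-rate scenarios
#'
#' Expands the full factorial design of sample sizes, segment lengths and
#' rho values, in deterministic order (sample size, then length, then rho
#' ascending, then replicate).
#'
#' @param sample_sizes haplotype counts.
#' @param lengths_bp segment lengths in bp.
#' @param rho_values per-bp rho values, all `>= 0`.
#' @param theta per-bp population mutation rate, `> 0`.
#' @param demography_tag `"neutral"` or `"bottleneck_growth"`.
#' @param replicates replicates per cell.
#' @param seed integer seed recorded with the grid.
#' @return A `data.frame` with one row per scenario: columns `n`,
#'   `length_bp`, `rho`, `theta`, `demography_tag`, `replicate`, `seed`.
#' @examples
#' nrow(scenario_grid(c(10, 16, 20), c(1000, 2000, 3000),
#'                    seq(0, 0.1, length.out = 111), 0.01))
#' @export
scenario_grid <- function(sample_sizes, lengths_bp, rho_values, theta,
                          demography_tag = c("neutral", "bottleneck_growth"),
                          replicates = 1, seed = 1) {
  demography_tag <- match.arg(demography_tag)
  if (!length(sample_sizes) || !length(lengths_bp) || !length(rho_values))
    stop("scenario factors must be non-empty")
  if (any(rho_values < 0)) stop("rho values must be >= 0")
  if (theta <= 0) stop("theta must be > 0")
  g <- expand.grid(replicate = seq_len(replicates),
                   rho = sort(rho_values),
                   length_bp = sort(lengths_bp),
                   n = sort(sample_sizes),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("n", "length_bp", "rho", "replicate")]
  g <- g[order(g$n, g$length_bp, g$rho, g$replicate), , drop = FALSE]
  rownames(g) <- NULL
  g$theta <- theta
  g$demography_tag <- demography_tag
  g$seed <- seed
  g
}

#' The constant-rate training/evaluation design
#'
#' Sample sizes (10, 16, 20), segment lengths (1, 2, 3) kb and 111 rho
#' values equidistant in `[0, 0.1]` at `theta = 0.01`: 999 scenarios per
#' replicate.
#'
#' @inheritParams scenario_grid
#' @export
constant_rate_grid <- function(theta = 0.01,
                               demography_tag = "neutral",
                               replicates = 1, seed = 1) {
  scenario_grid(c(10, 16, 20), c(1000, 2000, 3000),
                seq(0, 0.1, length.out = 111), theta,
                demography_tag, replicates, seed)
}

# ---- coalescent engine bridge -------------------------------------------

python_binary <- function() {
  p <- getOption("rhomap.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) stop("no python interpreter found; set options(rhomap.python=)")
  p
}

# msprime units for a demography under the package's haploid scaling
# (reference size 0.5; 1 coalescent unit = 0.5 generations)
demography_msprime <- function(dem) {
  if (is.null(dem)) return(list(pop_sizes = list(0.5), pop_times = list()))
  list(pop_sizes = as.list(0.5 * dem$relative_sizes),
       pop_times = as.list(0.5 * -dem$epoch_boundaries))
}

#' Simulate haplotype alignments from the coalescent
#'
#' Draws samples from the coalescent with recombination via the msprime
#' engine (called through a bundled Python helper in one batch process).
#' `simulate_alignment()` is the single-scenario convenience wrapper.
#'
#' @param maps a list of [recomb_map]s (or a single map, recycled).
#' @param n haplotype counts, recycled over scenarios.
#' @param theta per-bp mutation rates, recycled.
#' @param demography `NULL` for a constant-size population or a
#'   `demography_model`; may be a list, recycled.
#' @param seed integer seed; per-scenario engine seeds are derived from it,
#'   so identical calls give identical output.
#' @return A list of [hap_alignment] objects, one per scenario.
#' @export
simulate_alignments <- function(maps, n, theta, demography = NULL, seed = 1) {
  if (inherits(maps, "recomb_map")) maps <- list(maps)
  k <- max(length(maps), length(n), length(theta))
  maps <- rep_len(maps, k); n <- rep_len(n, k); theta <- rep_len(theta, k)
  dems <- if (is.null(demography) || inherits(demography, "demography_model"))
    rep_len(list(demography), k) else rep_len(demography, k)
  stopifnot(all(n >= 2), all(theta > 0))
  seeds <- derive_seeds(seed, k)
  scenarios <- lapply(seq_len(k), function(i) {
    m <- maps[[i]]
    c(list(id = sprintf("s%d", i), n = n[i], length_bp = m$length_bp,
           theta = theta[i],
           breaks = I(c(0, m$breakpoints)), rates = I(m$rates),
           seed = seeds[i]),
      demography_msprime(dems[[i]]))
  })
  batch <- tempfile(fileext = ".json"); out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(batch, out)), add = TRUE)
  jsonlite::write_json(list(scenarios = scenarios), batch,
                       auto_unbox = TRUE, digits = NA)
  helper <- system.file("python", "coalsim.py", package = "rhomap")
  status <- system2(python_binary(), c(shQuote(helper), shQuote(batch),
                                       shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(out))
    stop(sprintf("coalescent engine failed (exit %d) on a batch of %d scenarios",
                 status, k))
  parse_sim_output(out, k)
}

#' @rdname simulate_alignments
#' @param map a single [recomb_map].
#' @export
simulate_alignment <- function(map, n, theta, demography = NULL, seed = 1) {
  simulate_alignments(list(map), n, theta, demography, seed)[[1]]
}

# deterministic stream of engine seeds in [1, 2^31 - 3]
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 2L, k, replace = FALSE)
}

parse_sim_output <- function(path, k) {
  lines <- readLines(path)
  heads <- grep("^#scenario ", lines)
  if (length(heads) != k) stop("engine output truncated")
  ends <- c(heads[-1] - 1L, length(lines))
  lapply(seq_len(k), function(i) {
    hd <- strsplit(lines[heads[i]], " ", fixed = TRUE)[[1]]
    n <- as.integer(hd[3]); L <- as.numeric(hd[4]); S <- as.integer(hd[5])
    if (S == 0)
      return(hap_alignment(matrix(0L, n, 0), numeric(0), L))
    pos <- as.numeric(strsplit(sub("^@", "", lines[heads[i] + 1L]),
                               " ", fixed = TRUE)[[1]])
    hapl <- lines[(heads[i] + 2L):(heads[i] + 1L + n)]
    mat <- matrix(as.integer(unlist(strsplit(hapl, "", fixed = TRUE))),
                  nrow = n, byrow = TRUE)
    hap_alignment(mat, pos, L)
  })
}
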