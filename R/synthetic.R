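# ---- counter-based RNG -----------------------------------------------------
# Synthetic SAR fields are keyed to global lattice coordinates with a
# splitmix-style 32-bit hash, so that a cell's draw depends only on
# (seed, cell indices, stream). Clipping the extent therefore never shifts
# the values of the remaining cells. Arithmetic is done in doubles mod 2^32
# (exact: all intermediates < 2^53).

U32 <- 4294967296

mulmod32 <- function(a, b) {
  al <- a %% 65536
  ah <- (a - al) / 65536
  (al * b + ((ah * b) %% 65536) * 65536) %% U32
}

xor32 <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(as.integer(al), as.integer(bl)) +
    bitwXor(as.integer(ah), as.integer(bh)) * 65536
}

shr32 <- function(a, k) floor(a / 2^k)

mix32 <- function(z) {
  z <- mulmod32(xor32(z, shr32(z, 16)), 2246822507) # 0x85ebca6b
  z <- mulmod32(xor32(z, shr32(z, 13)), 3266489909) # 0xc2b2ae35
  xor32(z, shr32(z, 16))
}

# Uniform(0,1) draw keyed by (seed, i, j, stream); vectorized over i/j.
hash_uniform <- function(seed, i, j, stream) {
  z <- (seed %% U32 + mulmod32(stream %% U32, 2654435761)) %% U32
  z <- mix32((z + mulmod32(i %% U32, 2246822519)) %% U32)
  z <- mix32((z + mulmod32(j %% U32, 31)) %% U32)
  (z + 0.5) / U32
}

# ---- scenario --------------------------------------------------------------

DEFAULT_HABITAT_LABELS <- c(
  "Littoral rock and other hard substrata", "Littoral coarse sediment",
  "Littoral sand, muddy sand", "Littoral mud", "Littoral mixed sediments",
  "Coastal saltmarshes and saline reedbeds",
  "Littoral sediments dominated by aquatic angiosperms",
  "Sublittoral coarse sediment", "Sublittoral sand", "Sublittoral mud",
  "Sublittoral mixed sediments", "Biogenic reefs")

zone_of_label <- function(label) {
  ifelse(grepl("^(Littoral|Coastal)", label), "littoral", "sublittoral")
}

#' Define a synthetic assessment scenario
#'
#' A scenario fully specifies a reproducible synthetic study area: a habitat
#' mosaic over a rectangular extent, a c-square SAR field, and a per-habitat
#' carbon table. Defaults emulate a trawled shelf sea: about a third of cells
#' with no recorded effort and a long-tailed log-normal distribution of
#' positive swept-area ratios with short-range spatial autocorrelation.
#'
#' @param seed Integer seed; the same seed reproduces every output bit-for-bit.
#' @param extent `c(lon_min, lat_min, lon_max, lat_max)` in degrees, aligned
#'   to the c-square lattice.
#' @param n_habitats Number of distinct habitat types (<= `n_patches`).
#' @param n_patches Number of mosaic polygons.
#' @param habitat_weights Optional sampling weights over the habitat types.
#' @param zero_fraction Fraction of SAR cells with exactly zero effort.
#' @param sar_meanlog,sar_sdlog Log-normal parameters of positive SAR values.
#' @param autocorr_length Spatial autocorrelation length of the SAR field in
#'   degrees (0 disables smoothing).
#' @param nd_fraction Fraction of habitats whose carbon estimates are marked
#'   missing (n.d) in the synthetic carbon table.
#' @param resolution Grid resolution in degrees (c-squares: 0.05).
#' @param habitat_labels Habitat label pool (EUNIS level-3 style).
#' @return A `ccsa_scenario` list.
#' @export
synthetic_scenario <- function(seed, extent = c(-1, 54, 0, 55),
                               n_habitats = 6, n_patches = 24,
                               habitat_weights = NULL,
                               zero_fraction = 0.35,
                               sar_meanlog = 0, sar_sdlog = 1,
                               autocorr_length = 0.1,
                               nd_fraction = 0.15,
                               resolution = 0.05,
                               habitat_labels = DEFAULT_HABITAT_LABELS) {
  if (!is_scalar_number(seed)) abort_parameter("seed must be a single number")
  if (length(extent) != 4 || extent[1] >= extent[3] || extent[2] >= extent[4])
    abort_parameter("extent must be c(lon_min, lat_min, lon_max, lat_max) with positive spans")
  if (zero_fraction < 0 || zero_fraction > 1)
    abort_parameter("zero_fraction must lie in [0, 1]")
  if (n_habitats < 1) abort_parameter("n_habitats must be >= 1")
  if (n_habitats > n_patches)
    abort_parameter("n_habitats (%d) exceeds the number of mosaic patches (%d)",
                    n_habitats, n_patches)
  if (n_habitats > length(habitat_labels))
    abort_parameter("n_habitats exceeds the habitat label pool (%d)",
                    length(habitat_labels))
  if (!is.null(habitat_weights) && length(habitat_weights) != n_habitats)
    abort_parameter("habitat_weights must have length n_habitats")
  structure(
    list(seed = as.integer(seed), extent = as.numeric(extent),
         n_habitats = as.integer(n_habitats), n_patches = as.integer(n_patches),
         habitat_weights = habitat_weights %||% rep(1, n_habitats),
         zero_fraction = zero_fraction, sar_meanlog = sar_meanlog,
         sar_sdlog = sar_sdlog, autocorr_length = autocorr_length,
         nd_fraction = nd_fraction, resolution = resolution,
         habitat_labels = habitat_labels[seq_len(n_habitats)]),
    class = "ccsa_scenario")
}

#' Read a synthetic scenario from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [synthetic_scenario()].
#' @return A `ccsa_scenario`.
#' @export
read_scenario <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(synthetic_scenario, args)
}

# ---- habitat mosaic --------------------------------------------------------

#' Generate a synthetic habitat mosaic
#'
#' Seeded Voronoi tessellation of random points within the extent: a gapless,
#' non-overlapping set of convex polygons, each labelled with a habitat type
#' and its littoral/sublittoral zone. Every habitat type appears in at least
#' one patch.
#'
#' @param scenario A `ccsa_scenario`.
#' @return A `ccsa_map` of labelled polygons.
#' @export
generate_habitat_mosaic <- function(scenario) {
  ext <- scenario$extent
  n <- scenario$n_patches
  with_preserved_seed(scenario$seed, {
    px <- stats::runif(n, ext[1], ext[3])
    py <- stats::runif(n, ext[2], ext[4])
    lab_idx <- c(seq_len(scenario$n_habitats),
                 if (n > scenario$n_habitats)
                   sample.int(scenario$n_habitats, n - scenario$n_habitats,
                              replace = TRUE, prob = scenario$habitat_weights))
    lab_idx <- sample(lab_idx)
    base <- rect_poly(ext[1], ext[2], ext[3], ext[4])
    features <- lapply(seq_len(n), function(k) {
      cell <- base
      for (m in seq_len(n)) {
        if (m == k) next
        # keep the side of the perpendicular bisector nearer to point k
        a <- px[m] - px[k]; b <- py[m] - py[k]
        c <- (a * (px[m] + px[k]) + b * (py[m] + py[k])) / 2
        cell <- clip_halfplane(cell, a, b, c)
        if (nrow(cell) == 0) break
      }
      label <- scenario$habitat_labels[lab_idx[k]]
      list(habitat_label = label, zone = zone_of_label(label),
           polygons = list(cell), properties = list(patch = k))
    })
    features <- Filter(function(f) nrow(f$polygons[[1]]) >= 3, features)
    structure(list(features = features), class = "ccsa_map")
  })
}

# ---- SAR field -------------------------------------------------------------

#' Generate a synthetic swept-area-ratio field
#'
#' One cell per 0.05-degree lattice point within the extent. A configured
#' fraction of cells carries exactly zero effort (independent per cell);
#' positive values are log-normal, optionally smoothed with a Gaussian kernel
#' of the scenario's autocorrelation length (variance-preserving, so the
#' marginal distribution is unchanged). Draws are keyed to the global lattice
#' coordinates: generating on a sub-extent reproduces exactly the cells the
#' two extents share.
#'
#' @param scenario A `ccsa_scenario`.
#' @return A `ccsa_sar_grid`.
#' @export
generate_sar_field <- function(scenario) {
  ext <- scenario$extent
  r <- scenario$resolution
  align <- c(ext[1], ext[2], ext[3], ext[4]) / r
  if (any(abs(align - round(align)) > 1e-8))
    abort_parameter("extent must be aligned to the %g-degree lattice", r)

  i_rng <- round(ext[1] / r):(round(ext[3] / r) - 1L)
  j_rng <- round(ext[2] / r):(round(ext[4] / r) - 1L)

  pad <- 0L
  if (scenario$autocorr_length > 0) {
    L <- scenario$autocorr_length / r
    pad <- as.integer(ceiling(3 * L))
  }
  ip <- (min(i_rng) - pad):(max(i_rng) + pad)
  jp <- (min(j_rng) - pad):(max(j_rng) + pad)
  ii <- rep(ip, times = length(jp))
  jj <- rep(jp, each = length(ip))
  z <- matrix(stats::qnorm(hash_uniform(scenario$seed, ii, jj, 2)),
              nrow = length(ip), ncol = length(jp))
  if (pad > 0) {
    L <- scenario$autocorr_length / r
    k <- stats::dnorm(seq(-pad, pad), sd = L)
    k <- k / sqrt(sum(k^2))          # unit-variance smoothing
    smooth1 <- function(mat, kern) { # along rows, valid region only
      out <- matrix(0, nrow(mat) - 2 * pad, ncol(mat))
      for (d in seq_along(kern))
        out <- out + kern[d] * mat[d:(d + nrow(out) - 1L), , drop = FALSE]
      out
    }
    z <- smooth1(z, k)
    z <- t(smooth1(t(z), k))
  }
  iv <- rep(i_rng, times = length(j_rng))
  jv <- rep(j_rng, each = length(i_rng))
  zv <- as.vector(z)
  zero <- hash_uniform(scenario$seed, iv, jv, 1) < scenario$zero_fraction
  sar <- exp(scenario$sar_meanlog + scenario$sar_sdlog * zv)
  sar[zero] <- 0

  out <- data.frame(
    cell_id = sprintf("c_%d_%d", iv, jv),
    lon = (iv + 0.5) * r,
    lat = (jv + 0.5) * r,
    sar = sar)
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, resolution = r, class = c("ccsa_sar_grid", "data.frame"))
}

# ---- carbon table ----------------------------------------------------------

#' Generate a synthetic per-habitat carbon table
#'
#' Draws per-habitat mean organic-carbon stock (log-normal, kg C m^-2) and
#' accumulation (log-normal, kg C m^-2 yr^-1), marks a configured fraction of
#' habitats as having no data (n.d), and prepends the 0.00 dummy habitat.
#'
#' @param scenario A `ccsa_scenario`.
#' @return Component records suitable for [combine_components()].
#' @export
generate_carbon_table <- function(scenario) {
  labs <- scenario$habitat_labels
  with_preserved_seed(scenario$seed + 1L, {
    stock <- stats::rlnorm(length(labs), meanlog = 1, sdlog = 1)
    accum <- stats::rlnorm(length(labs), meanlog = -3, sdlog = 0.7)
    nd <- stats::runif(length(labs)) < scenario$nd_fraction
    stock[nd] <- NA; accum[nd] <- NA
    data.frame(
      habitat_label = c(DUMMY_LABEL, labs),
      component = "combined",
      oc_stock_kgCm2 = c(0, stock),
      oc_accumulation_kgCm2yr = c(0, accum))
  })
}

# ---- case-study fixture ----------------------------------------------------

#' Packaged case-study fixture
#'
#' Returns the twelve scoring elements of the southern North Sea case study
#' with the published UK-EEZ organic-carbon table (including the n.d markers
#' and the dummy zero habitat) and an attribute-score set. Attribute values
#' fixed by the published assessment (regeneration, natural disturbance with
#' the biogenic-reef override, the removability pair, gear footprint) carry
#' `source = "paper"`; every other value (substratum profile, overlap, SAR,
#' encounterability) is a synthetic mid-range placeholder
#' (`source = "placeholder"`) because the underlying per-element workbook is
#' not publicly reproduced. Results computed from this fixture exercise the
#' method; they are not the published case-study scores.
#'
#' @return List with `elements` (list of [scoring_element()]), `carbon`
#'   (combined `ccsa_carbon` table), `scores` (the long attribute table with
#'   provenance), and `gear` (`"dredge"`, the qualifier used throughout).
#' @export
case_study_fixture <- function() {
  carbon <- combine_components(read_carbon_table())
  scores <- utils::read.csv(
    system.file("extdata", "case_study_scores_synthetic.csv",
                package = "ccsa", mustWork = TRUE),
    stringsAsFactors = FALSE)
  elements <- elements_from_scores(scores)
  list(elements = elements, carbon = carbon, scores = scores, gear = "dredge")
}

#' Build scoring elements from a long attribute table
#'
#' @param scores Data.frame with columns `element_id`, `habitat_label`,
#'   `zone`, `attribute`, `value` (one row per element x attribute).
#' @return List of [scoring_element()] objects ordered by element id.
#' @export
elements_from_scores <- function(scores) {
  need <- c("element_id", "habitat_label", "zone", "attribute", "value")
  if (!all(need %in% names(scores)))
    abort_validation("attribute table must have columns: %s",
                     paste(need, collapse = ", "))
  ids <- sort(unique(scores$element_id))
  lapply(ids, function(id) {
    r <- scores[scores$element_id == id, , drop = FALSE]
    vals <- stats::setNames(as.numeric(r$value), r$attribute)
    scoring_element(id, r$habitat_label[1], r$zone[1], scores = vals)
  })
}
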