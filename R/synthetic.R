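#' Configuration for the synthetic salivary-proteome generator
#'
#' Bundles and validates the parameters of the cohort simulator. Defaults
#' mirror the shape of a label-free salivary proteomics case/control study:
#' 2815 proteoforms quantified in 10 case and 20 control samples, with about
#' 5\% of rows planted as differentially abundant markers, correlated protein
#' blocks (co-regulated communities), UniProt dash-suffixed isoform entries,
#' log-normal abundances and zero-encoded non-detection.
#'
#' @param n_cases,n_controls Samples per group.
#' @param n_proteins Total proteoform rows (isoform entries included).
#' @param n_markers Planted differential proteoforms; default is 5\% of
#'   `n_proteins` (rounded).
#' @param effect_log2fc Mean absolute log2 fold change of planted markers
#'   (default 2, within the fold-change range reported for salivary OSCC
#'   markers and large enough to be detectable at these group sizes).
#' @param block_size Proteins per correlated community.
#' @param block_rho Within-block noise correlation, in \[0, 1).
#' @param isoform_fraction Fraction of rows that are isoform entries of
#'   another row, in \[0, 1\].
#' @param noise_sd Residual SD on the log2 scale (> 0).
#' @param missing_rate Fraction of entries zeroed to emulate non-detection,
#'   in \[0, 1).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-protein
#'   baseline abundance on the log2 scale.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 10, n_controls = 20, n_proteins = 2815,
                             n_markers = NULL, effect_log2fc = 2,
                             block_size = 50, block_rho = 0.3,
                             isoform_fraction = 0.1, noise_sd = 1,
                             missing_rate = 0.1,
                             baseline_log2_mean = 20, baseline_log2_sd = 2,
                             seed = 1) {
  if (is.null(n_markers)) n_markers <- round(0.05 * n_proteins)
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_proteins = n_proteins, n_markers = n_markers,
              effect_log2fc = effect_log2fc, block_size = block_size,
              block_rho = block_rho, isoform_fraction = isoform_fraction,
              noise_sd = noise_sd, missing_rate = missing_rate,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, seed = seed)
  check <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, what), call. = FALSE)
  }
  check(n_cases >= 2, "n_cases", "need at least 2 samples per group")
  check(n_controls >= 2, "n_controls", "need at least 2 samples per group")
  check(n_proteins >= 1, "n_proteins", "must be positive")
  check(n_markers >= 0 && n_markers <= n_proteins, "n_markers",
        "must lie in [0, n_proteins]")
  check(effect_log2fc >= 0, "effect_log2fc", "must be nonnegative")
  check(block_size >= 1, "block_size", "must be at least 1")
  check(block_rho >= 0 && block_rho < 1, "block_rho", "must lie in [0, 1)")
  check(isoform_fraction >= 0 && isoform_fraction <= 1, "isoform_fraction",
        "must lie in [0, 1]")
  check(noise_sd > 0, "noise_sd", "must be positive")
  check(missing_rate >= 0 && missing_rate < 1, "missing_rate",
        "must lie in [0, 1)")
  check(is.numeric(seed) && length(seed) == 1, "seed", "must be a scalar")
  structure(cfg, class = "synthetic_config")
}

# UniProt-style synthetic accessions with dash-suffixed isoform entries.
# Returns a character vector of length n with round(isoform_fraction * n)
# isoform IDs whose bases are drawn from the non-isoform rows.
synth_accessions <- function(n, isoform_fraction) {
  n_iso <- round(isoform_fraction * n)
  n_base <- n - n_iso
  bases <- sprintf("P%05d", seq_len(n_base))
  if (n_iso == 0) return(bases)
  parents <- sample(bases, n_iso, replace = TRUE)
  idx <- stats::ave(seq_along(parents), parents, FUN = seq_along) + 1L
  c(bases, paste0(parents, "-", idx))
}

#' Simulate a case/control salivary proteoform abundance matrix
#'
#' Abundances are log-normal: a per-protein baseline on the log2 scale plus
#' equicorrelated within-block Gaussian noise (protein communities), with a
#' fixed +/- `effect_log2fc` shift added to the case samples of planted
#' marker rows. Values are exponentiated back to the natural scale and a
#' `missing_rate` fraction of entries is zeroed to emulate non-detection.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `matrix` (an [abundance_matrix]) and `truth`,
#'   the ground truth: `marker_ids`, `direction` (named "up"/"down" by
#'   marker), `planted_edges` (data.frame `a`,`b` of base accessions forming
#'   a path among markers, for the interactome generator), and
#'   `planted_set_id` (the enriched gene-set identifier).
#' @export
simulate_abundance <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  s <- config$n_cases + config$n_controls
  acc <- synth_accessions(n, config$isoform_fraction)
  samples <- c(sprintf("case_%02d", seq_len(config$n_cases)),
               sprintf("control_%02d", seq_len(config$n_controls)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(config$n_cases, config$n_controls)),
                            samples)

  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  block <- rep(seq_len(ceiling(n / config$block_size)),
               each = config$block_size)[seq_len(n)]
  n_blocks <- max(block)
  z <- matrix(stats::rnorm(n_blocks * s), n_blocks, s)      # shared per block
  e <- matrix(stats::rnorm(n * s), n, s)                    # idiosyncratic
  rho <- config$block_rho
  noise <- config$noise_sd * (sqrt(rho) * z[block, , drop = FALSE] +
                              sqrt(1 - rho) * e)

  markers <- if (config$n_markers > 0) sort(sample(n, config$n_markers))
             else integer(0)
  direction <- stats::setNames(sample(c(1, -1), length(markers),
                                      replace = TRUE), acc[markers])
  delta <- numeric(n)
  delta[markers] <- direction * config$effect_log2fc
  case_cols <- groups == "case"

  log2x <- baseline + noise
  log2x[, case_cols] <- log2x[, case_cols] + delta
  x <- 2^log2x
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(x)) < config$missing_rate
    x[drop] <- 0
  }
  dimnames(x) <- list(acc, samples)

  marker_ids <- acc[markers]
  marker_bases <- unique(proteoform_base(marker_ids))
  path_len <- min(10L, length(marker_bases))
  planted_edges <- if (path_len >= 2) {
    nodes <- sample(marker_bases, path_len)
    data.frame(a = nodes[-path_len], b = nodes[-1],
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }

  truth <- list(marker_ids = marker_ids,
                direction = ifelse(direction > 0, "up", "down"),
                planted_edges = planted_edges,
                planted_set_id = "PATHWAY_PLANTED")
  list(matrix = abundance_matrix(x, groups), truth = truth)
}

mitab_row <- function(a, b, taxid_a = 9606, taxid_b = 9606,
                      type_a = "psi-mi:\"MI:0326\"(protein)",
                      type_b = "psi-mi:\"MI:0326\"(protein)", idx = 1) {
  tax <- function(t) sprintf("taxid:%d(%s)", t,
                             if (t == 9606) "human" else "other")
  paste(sprintf("uniprotkb:%s", a), sprintf("uniprotkb:%s", b),
        "-", "-", "-", "-",
        "psi-mi:\"MI:0018\"(two hybrid)", "-", "pubmed:12345678",
        tax(taxid_a), tax(taxid_b),
        "psi-mi:\"MI:0915\"(physical association)",
        "psi-mi:\"MI:0469\"(IntAct)", sprintf("synth:E%06d", idx), "-",
        "-", "-", "-", "-", "-", type_a, type_b,
        sep = "\t")
}

#' Simulate a PSI-MI TAB interactome over a proteoform universe
#'
#' Writes tab-separated MITAB records (the 15 core columns plus interactor
#' type columns 21/22) containing: the ground truth's planted marker-marker
#' edges, uniform background edges, deliberate duplicate records (some with
#' swapped interactor order), self-loops, rows with a non-human taxon, and
#' rows with a non-protein interactor type -- the latter four categories
#' exist to exercise the downstream filters.
#'
#' @param truth Ground truth list from [simulate_abundance()] (uses
#'   `planted_edges`; may be `NULL` for a truth-free interactome).
#' @param universe Character vector of proteoform IDs edges are drawn from.
#' @param path Output MITAB file path.
#' @param background_edge_prob Probability that a random unordered pair of
#'   universe members is connected.
#' @param decoy_taxid_fraction Fraction of emitted rows given a non-9606
#'   taxon.
#' @param nonprotein_fraction Fraction of emitted rows given a non-protein
#'   interactor type.
#' @param duplicate_fraction Fraction of true rows re-emitted as duplicates.
#' @param n_self_loops Number of self-interaction rows appended.
#' @param seed Integer seed.
#' @return Invisibly, a data.frame describing every emitted row (`a`, `b`,
#'   raw IDs, taxids, types, and a `kind` flag in planted/background/
#'   duplicate/self_loop/decoy_taxid/nonprotein) for test bookkeeping.
#' @export
simulate_interactome <- function(truth, universe, path,
                                 background_edge_prob = 0.002,
                                 decoy_taxid_fraction = 0.05,
                                 nonprotein_fraction = 0.02,
                                 duplicate_fraction = 0.05,
                                 n_self_loops = 3, seed = 1) {
  if (length(universe) == 0)
    stop("`universe` must be non-empty", call. = FALSE)
  set.seed(seed)
  rows <- data.frame(a = character(0), b = character(0),
                     taxid_a = integer(0), taxid_b = integer(0),
                     protein_a = logical(0), protein_b = logical(0),
                     kind = character(0), stringsAsFactors = FALSE)
  add <- function(a, b, kind, taxid = 9606, protein = TRUE) {
    if (length(a) == 0) return(invisible(NULL))
    rows <<- rbind(rows, data.frame(
      a = a, b = b, taxid_a = taxid, taxid_b = taxid,
      protein_a = protein, protein_b = protein, kind = kind,
      stringsAsFactors = FALSE))
  }
  if (!is.null(truth) && nrow(truth$planted_edges) > 0)
    add(truth$planted_edges$a, truth$planted_edges$b, "planted")

  n_pairs <- length(universe) * (length(universe) - 1) / 2
  n_bg <- round(background_edge_prob * n_pairs)
  if (n_bg > 0) {
    ia <- sample(universe, n_bg, replace = TRUE)
    ib <- sample(universe, n_bg, replace = TRUE)
    keep <- ia != ib
    add(ia[keep], ib[keep], "background")
  }
  n_real <- nrow(rows)
  if (n_real > 0 && duplicate_fraction > 0) {
    ndup <- max(1L, round(duplicate_fraction * n_real))
    pick <- sample(n_real, ndup, replace = TRUE)
    swap <- stats::runif(ndup) < 0.5
    add(ifelse(swap, rows$b[pick], rows$a[pick]),
        ifelse(swap, rows$a[pick], rows$b[pick]), "duplicate")
  }
  if (n_self_loops > 0) {
    loops <- sample(universe, min(n_self_loops, length(universe)))
    add(loops, loops, "self_loop")
  }
  n_now <- nrow(rows)
  n_decoy <- round(decoy_taxid_fraction * n_now)
  if (n_decoy > 0)
    add(sample(universe, n_decoy, replace = TRUE),
        sample(universe, n_decoy, replace = TRUE),
        "decoy_taxid", taxid = 10090L)
  n_nonprot <- round(nonprotein_fraction * n_now)
  if (n_nonprot > 0)
    add(sample(universe, n_nonprot, replace = TRUE),
        sample(universe, n_nonprot, replace = TRUE),
        "nonprotein", protein = FALSE)

  lines <- vapply(seq_len(nrow(rows)), function(i) {
    type <- function(p) if (p) "psi-mi:\"MI:0326\"(protein)"
                        else "psi-mi:\"MI:0250\"(gene)"
    mitab_row(rows$a[i], rows$b[i], rows$taxid_a[i], rows$taxid_b[i],
              type(rows$protein_a[i]), type(rows$protein_b[i]), idx = i)
  }, character(1))
  writeLines(lines, path)
  invisible(rows)
}

#' Simulate a GMT gene-set collection with one marker-enriched set
#'
#' One set (named by `truth$planted_set_id`) is stacked with marker base
#' accessions; the remaining sets are uniform draws from the universe.
#'
#' @param truth Ground truth list from [simulate_abundance()]; `NULL` for a
#'   fully null collection.
#' @param universe Character vector of accessions sets are drawn from
#'   (collapsed to base accessions internally).
#' @param path Output GMT file path.
#' @param n_sets Number of gene sets (>= 1), planted set included.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param marker_coverage Fraction of marker bases included in the planted
#'   set.
#' @param seed Integer seed.
#' @return Invisibly, the named list of member vectors written.
#' @export
simulate_gene_sets <- function(truth, universe, path, n_sets = 50,
                               set_size_range = c(10, 50),
                               marker_coverage = 0.8, seed = 1) {
  if (n_sets < 1) stop("`n_sets` must be at least 1", call. = FALSE)
  bases <- unique(proteoform_base(universe))
  if (max(set_size_range) > length(bases))
    stop("set size range exceeds the universe size", call. = FALSE)
  set.seed(seed)
  sets <- list()
  if (!is.null(truth) && length(truth$marker_ids) > 0) {
    mb <- unique(proteoform_base(truth$marker_ids))
    core <- sample(mb, max(1L, round(marker_coverage * length(mb))))
    pad <- max(0L, min(set_size_range) - length(core))
    members <- unique(c(core, sample(setdiff(bases, core), pad)))
    sets[[truth$planted_set_id]] <- members
  }
  while (length(sets) < n_sets) {
    size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    id <- sprintf("RANDOM_SET_%03d", length(sets) + 1L)
    sets[[id]] <- sample(bases, size)
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, paste0(id, " (synthetic)"), sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Write or read the simulator's ground truth as JSON
#'
#' @param truth Ground truth list from [simulate_abundance()].
#' @param path JSON file path.
#' @return `write_ground_truth` returns the path invisibly;
#'   `read_ground_truth` returns the truth list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(marker_ids = truth$marker_ids,
         direction = as.list(truth$direction),
         planted_edges = truth$planted_edges,
         planted_set_id = truth$planted_set_id),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$direction <- unlist(x$direction)
  if (length(x$planted_edges) == 0)
    x$planted_edges <- data.frame(a = character(0), b = character(0),
                                  stringsAsFactors = FALSE)
  x
}
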