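# Self-contained synthetic datasets with the statistical structure the
# pipeline assumes: two class-conditioned residue-composition distributions
# (so the physicochemical features are separable), random 1-4 domain
# architectures, and log-normal lambda scores with a higher location for
# interacting pairs, floored at the 1.5 interaction cutoff.

#' Synthetic-dataset configuration
#'
#' Defaults mirror the published dataset's shape: 427 positive / 403 negative
#' protein pairs and 1040/1040 domain pairs. The class signal is planted in
#' both channels — sequence composition (tilted along the hydropathy axis by
#' `composition_tilt`) feeds the SVM features, and the lambda distributions
#' (`exp(Normal(mu, sd))`, interacting mean above background) feed `d_mn` —
#' so the score fusion is genuinely exercised. Either channel can be switched
#' off (`composition_tilt = 0`; `lambda_mu_pos = lambda_mu_bg` with
#' `lambda_floor = 0`) to produce a null dataset.
#'
#' @param n_proteins proteins per class pool
#' @param n_domains distinct domains per class pool
#' @param domain_range min/max domains per protein (uniform)
#' @param n_positive_pairs,n_negative_pairs protein-pair counts
#' @param n_positive_ddi,n_negative_ddi labeled domain-pair counts
#' @param seq_len_range sequence length range (uniform)
#' @param composition_tilt residue sampling weight `exp(tilt * hydropathy)`
#'   for interacting-class domains; 0 = no sequence signal
#' @param lambda_mu_pos,lambda_mu_bg,lambda_sd log-scale lambda parameters
#' @param lambda_floor interacting lambdas are floored here (the interaction
#'   cutoff); set 0 to disable
#' @param neg_score_frac fraction of negative-pair domain pairs that carry a
#'   (background-distributed) table score; the rest fall back to the table's
#'   background value at lookup
#' @param seed integer seed; a fixed seed gives a bit-identical dataset
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_proteins = 300L, n_domains = 350L,
                         domain_range = c(1L, 4L),
                         n_positive_pairs = 427L, n_negative_pairs = 403L,
                         n_positive_ddi = 1040L, n_negative_ddi = 1040L,
                         seq_len_range = c(50L, 300L),
                         composition_tilt = 0.25,
                         lambda_mu_pos = log(50), lambda_mu_bg = log(1.2),
                         lambda_sd = 0.8, lambda_floor = 1.5,
                         neg_score_frac = 0.3, seed = 42L) {
  stopifnot(n_proteins >= 2L, n_domains >= 1L,
            n_positive_pairs >= 1L, n_negative_pairs >= 1L,
            lambda_mu_pos >= lambda_mu_bg, lambda_sd > 0)
  structure(as.list(environment()), class = "synth_config")
}

.sample_seq <- function(len, prob) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = prob), collapse = "")
}

# distinct unordered pairs sampled from a pool of ids
.sample_pairs <- function(ids, n_pairs) {
  n <- length(ids)
  max_pairs <- n * (n - 1) / 2
  if (n_pairs > max_pairs)
    stop("cannot draw ", n_pairs, " distinct pairs from ", n, " ids")
  seen <- character(0L)
  out_a <- character(n_pairs); out_b <- character(n_pairs)
  k <- 0L
  while (k < n_pairs) {
    pick <- sample(ids, 2L)
    key <- paste(sort(pick), collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- k + 1L
    out_a[k] <- pick[1L]; out_b[k] <- pick[2L]
  }
  data.frame(id_a = out_a, id_b = out_b, stringsAsFactors = FALSE)
}

# every unique unordered domain pair reachable from a protein-pair table
.reachable_domain_pairs <- function(pairs, architectures) {
  arch <- architectures
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    da <- arch[[pairs$id_a[i]]]; db <- arch[[pairs$id_b[i]]]
    g <- expand.grid(a = da, b = db, stringsAsFactors = FALSE)
    out[[i]] <- data.frame(id_a = pmin(g$a, g$b), id_b = pmax(g$a, g$b))
  }
  dp <- do.call(rbind, out)
  dp[!duplicated(paste(dp$id_a, dp$id_b, sep = "\r")), , drop = FALSE]
}

#' Generate a complete synthetic dataset
#'
#' Produces, mutually consistent: domain sequences (FASTA-writable), protein
#' architectures, labeled DDI and PPI pair tables, a lambda score table, and
#' per-domain location annotations. All randomness flows from `config$seed`.
#'
#' @param config a [synth_config()]
#' @return object of class `synth_dataset`: list with `sequences` (named list
#'   of [domain_sequence()]), `architectures` (named list of character
#'   vectors), `proteins` (named list of [protein_record()]), `ddi_pairs`,
#'   `ppi_pairs` (data frames with `id_a`, `id_b`, `label`), `scores`
#'   (data frame `id_a`, `id_b`, `lambda`), `locations` (data frame
#'   `domain_id`, `location`), `config`
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cfg <- config

  # residue-composition distributions: uniform background, hydropathy-tilted
  # interacting class
  p_bg <- rep(1 / 20, 20L)
  w <- exp(cfg$composition_tilt * kyte_doolittle()[AA_ALPHABET])
  p_int <- w / sum(w)

  dom_ids <- list(
    int = sprintf("DI%04d", seq_len(cfg$n_domains)),
    bg  = sprintf("DB%04d", seq_len(cfg$n_domains)))
  lens <- function(n) sample(seq(cfg$seq_len_range[1L], cfg$seq_len_range[2L]),
                             n, replace = TRUE)
  seqs <- c(
    lapply(stats::setNames(lens(cfg$n_domains), dom_ids$int),
           .sample_seq, prob = p_int),
    lapply(stats::setNames(lens(cfg$n_domains), dom_ids$bg),
           .sample_seq, prob = p_bg))
  sequences <- Map(domain_sequence, names(seqs), seqs)

  prot_ids <- list(
    int = sprintf("PI%04d", seq_len(cfg$n_proteins)),
    bg  = sprintf("PB%04d", seq_len(cfg$n_proteins)))
  draw_arch <- function(pool) {
    k <- sample(seq(cfg$domain_range[1L], cfg$domain_range[2L]), 1L)
    sample(pool, k, replace = TRUE)
  }
  architectures <- c(
    stats::setNames(lapply(prot_ids$int, function(p) draw_arch(dom_ids$int)),
                    prot_ids$int),
    stats::setNames(lapply(prot_ids$bg, function(p) draw_arch(dom_ids$bg)),
                    prot_ids$bg))
  proteins <- Map(protein_record, names(architectures), architectures)

  ppi_pos <- .sample_pairs(prot_ids$int, cfg$n_positive_pairs)
  ppi_neg <- .sample_pairs(prot_ids$bg, cfg$n_negative_pairs)
  ppi_pairs <- rbind(cbind(ppi_pos, label = 1L), cbind(ppi_neg, label = 0L))

  dp_pos <- .reachable_domain_pairs(ppi_pos, architectures)
  dp_neg <- .reachable_domain_pairs(ppi_neg, architectures)
  if (nrow(dp_pos) < cfg$n_positive_ddi)
    stop("only ", nrow(dp_pos), " positive domain pairs constructible, ",
         cfg$n_positive_ddi, " requested")
  if (nrow(dp_neg) < cfg$n_negative_ddi)
    stop("only ", nrow(dp_neg), " negative domain pairs constructible, ",
         cfg$n_negative_ddi, " requested")
  ddi_pairs <- rbind(
    cbind(dp_pos[sample(nrow(dp_pos), cfg$n_positive_ddi), ], label = 1L),
    cbind(dp_neg[sample(nrow(dp_neg), cfg$n_negative_ddi), ], label = 0L))
  rownames(ddi_pairs) <- NULL

  # lambda scores: every positive-reachable domain pair gets an interacting
  # lambda (floored at the cutoff); a fraction of negative-reachable pairs
  # carry a background-distributed score, the rest stay out of the table
  lam_pos <- exp(stats::rnorm(nrow(dp_pos), cfg$lambda_mu_pos, cfg$lambda_sd))
  lam_pos <- pmax(lam_pos, cfg$lambda_floor)
  n_neg_scored <- round(cfg$neg_score_frac * nrow(dp_neg))
  neg_scored <- dp_neg[sample(nrow(dp_neg), n_neg_scored), , drop = FALSE]
  lam_neg <- exp(stats::rnorm(n_neg_scored, cfg$lambda_mu_bg, cfg$lambda_sd))
  scores <- rbind(cbind(dp_pos, lambda = lam_pos),
                  cbind(neg_scored, lambda = lam_neg))
  rownames(scores) <- NULL

  locations <- data.frame(
    domain_id = names(sequences),
    location = sample(names(location_codes()), length(sequences),
                      replace = TRUE))

  structure(list(sequences = sequences, architectures = architectures,
                 proteins = proteins, ddi_pairs = ddi_pairs,
                 ppi_pairs = ppi_pairs, scores = scores,
                 locations = locations, config = cfg),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synth_dataset: %d domains, %d proteins, ",
                     "%d ppi pairs, %d ddi pairs, seed %d>\n"),
              length(x$sequences), length(x$proteins), nrow(x$ppi_pairs),
              nrow(x$ddi_pairs), x$config$seed))
  invisible(x)
}

#' Ground-truth labels of a generated dataset
#'
#' @param dataset a `synth_dataset`
#' @return list with `ppi` and `ddi` data frames (`id_a`, `id_b`, `label`),
#'   exactly as drawn at generation time
#' @export
truth_table <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  list(ppi = dataset$ppi_pairs, ddi = dataset$ddi_pairs)
}

#' Write a generated dataset to a directory in the pipeline's file formats
#'
#' Emits `domains.fasta`, `architectures.tsv`, `ddi_pairs.tsv`,
#' `ppi_pairs.tsv`, `scores.tsv`, `locations.tsv`, and `manifest.tsv`
#' (the config and seed).
#'
#' @param dataset a `synth_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_domains(dataset$sequences, file.path(dir, "domains.fasta"))
  arch <- data.frame(protein_id = names(dataset$architectures),
                     domain_ids = vapply(dataset$architectures, paste,
                                         character(1L), collapse = ","))
  .write_tsv(arch, file.path(dir, "architectures.tsv"))
  .write_tsv(dataset$ddi_pairs, file.path(dir, "ddi_pairs.tsv"))
  .write_tsv(dataset$ppi_pairs, file.path(dir, "ppi_pairs.tsv"))
  sc <- dataset$scores
  sc$lambda <- sprintf("%.6g", sc$lambda)
  .write_tsv(sc, file.path(dir, "scores.tsv"))
  .write_tsv(dataset$locations, file.path(dir, "locations.tsv"))
  cfg <- dataset$config
  manifest <- data.frame(
    key = names(unclass(cfg)),
    value = vapply(unclass(cfg), function(v) paste(format(v, digits = 15),
                                                   collapse = ","),
                   character(1L)))
  .write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
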