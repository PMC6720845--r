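# Physicochemical properties of a domain sequence, computed directly from the
# amino-acid string: a self-contained equivalent of the classic Expasy
# ProtParam calculator, restricted to the 20 standard residues.

#' Construct a validated domain sequence
#'
#' @param domain_id non-empty string identifier (e.g. a Pfam accession)
#' @param sequence amino-acid string over the 20 standard one-letter codes;
#'   lowercase letters are uppercased. Ambiguity codes (B, J, O, U, X, Z) and
#'   any other character are rejected with the offending position named,
#'   because silently skipping residues would shift every mole-percent
#'   derived feature.
#' @return an object of class `domain_sequence` (list with `domain_id`,
#'   `sequence`)
#' @export
domain_sequence <- function(domain_id, sequence) {
  if (!is.character(domain_id) || length(domain_id) != 1L || !nzchar(domain_id))
    stop("domain_id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    stop("sequence of '", domain_id, "' is empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop("invalid residue '", chars[bad[1L]], "' at position ", bad[1L],
         " in '", domain_id, "' (only the 20 standard codes are accepted)")
  structure(list(domain_id = domain_id, sequence = sequence),
            class = "domain_sequence")
}

#' @export
print.domain_sequence <- function(x, ...) {
  cat(sprintf("<domain %s: %d aa>\n", x$domain_id, nchar(x$sequence)))
  invisible(x)
}

.seq_chars <- function(seq) {
  if (inherits(seq, "domain_sequence")) seq <- seq$sequence
  seq <- toupper(seq)
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

.as_domain_sequence <- function(seq) {
  if (inherits(seq, "domain_sequence")) return(seq)
  domain_sequence("unnamed", seq)
}

#' Count residues
#'
#' @param seq a `domain_sequence` or a plain amino-acid string
#' @return list with `counts` (named integer vector over the full 20-letter
#'   alphabet, zeros included) and `n_residues`
#' @export
count_residues <- function(seq) {
  seq <- .as_domain_sequence(seq)
  chars <- .seq_chars(seq)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- stats::setNames(as.integer(counts), AA_ALPHABET)
  list(counts = counts, n_residues = length(chars))
}

#' Charged residue counts
#'
#' Negative = Asp + Glu, positive = Arg + Lys. Histidine is not counted,
#' following the ProtParam convention.
#' @inheritParams count_residues
#' @return named numeric vector `c(n_negative, n_positive)`
#' @export
charged_counts <- function(seq) {
  cnt <- count_residues(seq)$counts
  c(n_negative = unname(cnt["D"] + cnt["E"]),
    n_positive = unname(cnt["R"] + cnt["K"]))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the ionizable
#' side chains (D, E, C, Y, H, K, R) with the Bjellqvist pKa set. Strictly
#' decreasing in pH.
#'
#' @inheritParams count_residues
#' @param ph pH value(s)
#' @param pka pKa table as returned by [pka_set()]
#' @return net charge (vectorized over `ph`)
#' @export
net_charge <- function(seq, ph, pka = pka_set()) {
  cnt <- count_residues(seq)$counts
  vapply(ph, function(p) {
    z <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      n <- if (g == "Nterm" || g == "Cterm") 1L else cnt[[g]]
      if (n == 0L) next
      if (pka$sign[i] > 0) {
        z <- z + n / (1 + 10^(p - pka$pka[i]))       # protonated fraction
      } else {
        z <- z - n / (1 + 10^(pka$pka[i] - p))       # deprotonated fraction
      }
    }
    z
  }, numeric(1L))
}

#' Theoretical isoelectric point
#'
#' pH at which [net_charge()] is zero, found by bisection on (0, 14).
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units
#' @param max_iter iteration cap
#' @return pI in pH units
#' @export
theoretical_pi <- function(seq, pka = pka_set(), tol = 0.001, max_iter = 100L) {
  lo <- 0; hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Molar extinction coefficients at 280 nm
#'
#' Gill-von Hippel coefficients: 5500 per Trp, 1490 per Tyr, 125 per cystine.
#' `ext1` assumes every cysteine is paired into cystine (pairs =
#' `floor(#Cys / 2)`); `ext2` assumes all cysteines reduced.
#'
#' @inheritParams count_residues
#' @return named vector `c(ext1, ext2)` in M^-1 cm^-1
#' @export
extinction_coefficients <- function(seq) {
  cnt <- count_residues(seq)$counts
  ext2 <- 5500 * cnt[["W"]] + 1490 * cnt[["Y"]]
  c(ext1 = ext2 + 125 * (cnt[["C"]] %/% 2L), ext2 = ext2)
}

#' Instability index
#'
#' Guruprasad statistic: `10/L * sum` of the dipeptide instability weight
#' values over the `L - 1` overlapping dipeptides.
#'
#' @inheritParams count_residues
#' @return dimensionless index (> ~40 suggests an unstable protein in vitro)
#' @export
instability_index <- function(seq) {
  chars <- .seq_chars(.as_domain_sequence(seq))
  L <- length(chars)
  if (L < 2L) stop("instability index requires at least 2 residues")
  w <- diwv_table()
  idx <- cbind(chars[-L], chars[-1L])
  10 / L * sum(w[idx])
}

#' Aliphatic index
#'
#' Ikai formula `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` over mole percents.
#' @inheritParams count_residues
#' @return dimensionless index in `[0, 390]`
#' @export
aliphatic_index <- function(seq) {
  r <- count_residues(seq)
  x <- 100 * r$counts / r$n_residues
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues.
#' @inheritParams count_residues
#' @return value in `[-4.5, 4.5]`
#' @export
gravy <- function(seq) {
  chars <- .seq_chars(.as_domain_sequence(seq))
  mean(kyte_doolittle()[chars])
}

#' Total atom count of the peptide
#'
#' Sum of in-chain residue atoms (free amino acid minus H2O, i.e. minus 3
#' atoms) plus the 3 atoms of the one water restored at the termini, so a
#' single residue equals its free amino acid.
#' @inheritParams count_residues
#' @return integer atom count
#' @export
atom_count <- function(seq) {
  cnt <- count_residues(seq)$counts
  atoms <- residue_atoms()
  sum(cnt * (atoms[names(cnt)] - 3L)) + 3L
}

#' Molecular weight (average isotopic)
#'
#' Sum of in-chain residue masses plus one water ([WATER_MASS]).
#' @inheritParams count_residues
#' @return mass in Da
#' @export
molecular_weight <- function(seq) {
  cnt <- count_residues(seq)$counts
  mass <- residue_masses()
  sum(cnt * (mass[names(cnt)] - WATER_MASS)) + WATER_MASS
}

#' Compute the full physicochemical profile of a domain
#'
#' @param seq a `domain_sequence` (length >= 2) or plain string
#' @return object of class `physchem_profile`: list with `domain_id`,
#'   `n_residues`, `theoretical_pi`, `n_negative`, `n_positive`, `n_atoms`,
#'   `ext_coefficient_1`, `instability_index`, `aliphatic_index`, `gravy`,
#'   `molecular_weight`, `ext_coefficient_2`, `aa_composition` (mole percent,
#'   sums to 100)
#' @export
compute_profile <- function(seq) {
  seq <- .as_domain_sequence(seq)
  r <- count_residues(seq)
  if (r$n_residues < 2L)
    stop("profile requires a sequence of length >= 2 ('", seq$domain_id, "')")
  ch <- charged_counts(seq)
  ext <- extinction_coefficients(seq)
  structure(list(
    domain_id         = seq$domain_id,
    n_residues        = r$n_residues,
    theoretical_pi    = theoretical_pi(seq),
    n_negative        = unname(ch["n_negative"]),
    n_positive        = unname(ch["n_positive"]),
    n_atoms           = atom_count(seq),
    ext_coefficient_1 = unname(ext["ext1"]),
    instability_index = instability_index(seq),
    aliphatic_index   = aliphatic_index(seq),
    gravy             = gravy(seq),
    molecular_weight  = molecular_weight(seq),
    ext_coefficient_2 = unname(ext["ext2"]),
    aa_composition    = 100 * r$counts / r$n_residues
  ), class = "physchem_profile")
}

#' Profile table for a set of domains
#'
#' @param seqs list of `domain_sequence` objects (e.g. from
#'   [read_fasta_domains()])
#' @return data frame, one row per domain, deterministic column order
#' @export
profile_table <- function(seqs) {
  rows <- lapply(seqs, function(s) {
    p <- compute_profile(s)
    comp <- as.list(p$aa_composition)
    names(comp) <- paste0("pct_", names(p$aa_composition))
    c(list(domain_id = p$domain_id),
      p[c("n_residues", "molecular_weight", "n_atoms", "theoretical_pi",
          "n_negative", "n_positive", "ext_coefficient_1", "ext_coefficient_2",
          "instability_index", "aliphatic_index", "gravy")],
      comp)
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}
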