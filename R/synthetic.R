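#' The 35 redox genes of the model
#'
#' The 14 mapped genes (rate-scaled and abundance-set) plus the remaining
#' redox genes carried in the expression matrix.
#'
#' @return Character vector of 35 gene symbols.
#' @export
redox_genes <- function() {
  c("NQO1", "SOD1", "POR", "AQP3", "GSR", "TXNRD1", "G6PD", "GLUD1",
    "GPX1", "CAT", "PRX1", "PRX2", "TXN", "GLRX",
    "NFE2L2", "KEAP1", "GCLC", "GCLM", "GSS", "GPX2", "GPX4", "PRDX4",
    "PRDX6", "TXN2", "TXNRD2", "SRXN1", "GLRX2", "GSTP1", "GSTM1",
    "MGST1", "IDH1", "ME1", "PGD", "AQP1", "SLC7A11")
}

#' Default per-gene base mean expression
#'
#' Relative normalized-expression scales reflecting typical transcript
#' abundance of the redox panel: thioredoxin, peroxiredoxins, and SOD1 are
#' abundant; membrane channels and some oxidoreductases are lowly expressed.
#' Genes not listed default to `fill`.
#'
#' @param genes Gene symbols.
#' @param fill Mean for genes without a specific entry.
#' @return Named numeric vector over `genes`.
#' @export
default_base_means <- function(genes = redox_genes(), fill = 3) {
  known <- c(NQO1 = 5, SOD1 = 15, POR = 3, AQP3 = 2, GSR = 4, TXNRD1 = 5,
             G6PD = 8, GLUD1 = 8, GPX1 = 12, CAT = 6, PRX1 = 15, PRX2 = 10,
             TXN = 20, GLRX = 3)
  out <- stats::setNames(rep(fill, length(genes)), genes)
  out[intersect(names(known), genes)] <- known[intersect(names(known), genes)]
  out
}

#' Design of a synthetic patient cohort
#'
#' Describes a patient-structured single-cell expression matrix standing in
#' for a tumor scRNA-seq cohort: lognormal per-gene expression with additive
#' log-scale patient offsets and malignant-class log-fold-changes, Bernoulli
#' dropout zero inflation, two cell classes per patient.
#'
#' @param n_patients Number of patients (default 10).
#' @param cells_per_class Cells per patient per class (default 50, giving
#'   100 cells per patient).
#' @param genes Gene symbols (default the 35 redox genes).
#' @param base_mean Named (or scalar) per-gene base mean expression.
#' @param dispersion Lognormal cell-level SD on the log scale; scalar or named
#'   per gene. The default gives NQO1 a larger dispersion than the other
#'   genes, emulating the pronounced NQO1 expression heterogeneity of tumor
#'   cells under variable Nrf2 activation.
#' @param patient_sd SD of per-patient, per-gene random offsets (log scale).
#' @param malignant_lfc Named per-gene natural-log fold-change implanted in
#'   malignant cells. The default up-shifts NQO1 by `log(4)`: NQO1 is
#'   constitutively several-fold overexpressed in solid tumors relative to
#'   adjacent non-malignant tissue.
#' @param dropout Dropout (zero-inflation) probability in [0, 1).
#' @param seed Integer seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_patients = 10, cells_per_class = 50,
                          genes = redox_genes(),
                          base_mean = default_base_means(genes),
                          dispersion = c(NQO1 = 1.0, .default = 0.5),
                          patient_sd = 0.3,
                          malignant_lfc = c(NQO1 = log(4)),
                          dropout = 0.3, seed = 1L) {
  stopifnot(n_patients >= 1, cells_per_class >= 1,
            dropout >= 0, dropout < 1, all(dispersion >= 0), patient_sd >= 0)
  if (length(base_mean) == 1) base_mean <- stats::setNames(
    rep(base_mean, length(genes)), genes)
  disp <- stats::setNames(
    rep(if (".default" %in% names(dispersion)) dispersion[[".default"]]
        else if (is.null(names(dispersion))) dispersion[[1]] else 0,
        length(genes)), genes)
  named <- setdiff(names(dispersion), ".default")
  disp[intersect(named, genes)] <- dispersion[intersect(named, genes)]
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  lfc[names(malignant_lfc)] <- malignant_lfc
  structure(list(n_patients = n_patients, cells_per_class = cells_per_class,
                 genes = genes, base_mean = base_mean[genes],
                 dispersion = disp, patient_sd = patient_sd,
                 malignant_lfc = lfc, dropout = dropout,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a synthetic single-cell cohort
#'
#' Expression is `exp(log(base mean) + patient offset + class * LFC +
#' cell noise)`, then zero-inflated by dropout. Dropout is
#' expression-dependent -- the probability of losing an observation decays
#' exponentially with the underlying expression level, the standard detection
#' model for scRNA-seq zero inflation -- with a single cohort-wide decay
#' constant calibrated so the expected overall zero rate equals the design's
#' `dropout` value; abundant transcripts therefore show few zeros and lowly
#' expressed ones many, as in real data. Deterministic given the design seed. The realized pre-dropout
#' matrix, implanted fold-changes, and patient offsets are returned as ground
#' truth.
#'
#' @param design A `cohort_design`.
#' @return List with `matrix` (gene x cell), `annotations` (data.frame:
#'   cell_id, patient_id, malignant), and `truth` (pre-dropout matrix,
#'   malignant_lfc, patient_offsets).
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)

  G <- length(design$genes)
  n_cells <- design$n_patients * design$cells_per_class * 2L
  patients <- sprintf("P%02d", seq_len(design$n_patients))
  ann <- data.frame(
    cell_id = sprintf("C%05d", seq_len(n_cells)),
    patient_id = rep(patients, each = design$cells_per_class * 2L),
    malignant = rep(rep(c(0L, 1L), each = design$cells_per_class),
                    times = design$n_patients),
    stringsAsFactors = FALSE)

  offsets <- matrix(stats::rnorm(G * design$n_patients, 0, design$patient_sd),
                    nrow = G, dimnames = list(design$genes, patients))
  logmu <- log(design$base_mean)[design$genes]

  lm <- matrix(logmu, G, n_cells) +
    offsets[, ann$patient_id, drop = FALSE] +
    outer(design$malignant_lfc[design$genes], ann$malignant) +
    matrix(stats::rnorm(G * n_cells), G, n_cells) * design$dispersion[design$genes]
  pre <- exp(lm)
  dimnames(pre) <- list(design$genes, ann$cell_id)

  drop_p <- matrix(0, G, n_cells)
  if (design$dropout > 0) {
    lam <- stats::uniroot(function(l) mean(exp(-l * pre)) - design$dropout,
                          lower = 0, upper = 1e6 / stats::median(pre),
                          tol = 1e-12)$root
    drop_p[] <- exp(-lam * pre)
  }
  keep <- matrix(stats::runif(G * n_cells), G, n_cells) >= drop_p
  mat <- pre * keep

  list(matrix = mat, annotations = ann,
       truth = list(pre_dropout = pre, malignant_lfc = design$malignant_lfc,
                    patient_offsets = offsets))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic per-gene rate-constant table
#'
#' Plausible positive constants for testing the protein-abundance model:
#' translation rates log-uniform on 1-100 per hour, protein half-lives
#' log-uniform on 1-100 h (degradation `log(2)/half-life`), mRNA rates on
#' matching scales. Deterministic given the seed.
#'
#' @param genes Gene symbols.
#' @param seed Integer seed.
#' @return data.frame with columns gene, k_sp, k_dp, k_sr, k_dr.
#' @export
generate_rate_constant_table <- function(genes = redox_genes(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(genes)
  lu <- function(lo, hi, n) exp(stats::runif(n, log(lo), log(hi)))
  data.frame(gene = genes,
             k_sp = lu(1, 100, n),
             k_dp = log(2) / lu(1, 100, n),
             k_sr = lu(0.5, 5, n),
             k_dr = log(2) / lu(2, 12, n),
             stringsAsFactors = FALSE)
}
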