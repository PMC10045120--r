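#' Read a gene-to-model mapping configuration
#'
#' The mapping declares which genes scale which rate constants
#' (`rate_scaled`), which genes set initial enzyme abundances
#' (`abundance_set`) with the species pools they control (`pools`), the
#' multiplier floor `multiplier_epsilon`, and the global expression scale.
#' `"A+B"` gene entries act additively on the summed expression.
#'
#' @param path YAML path; defaults to the packaged mapping.
#' @return A nested list.
#' @export
read_mapping_config <- function(path = system.file(
  "extdata", "mapping_default.yaml", package = "redoxcell", mustWork = TRUE)) {
  yaml::read_yaml(path)
}

#' Genes required by a mapping
#'
#' @param mapping A mapping config from [read_mapping_config()].
#' @return Character vector of the mapped genes (14 by default).
#' @export
mapped_genes <- function(mapping) {
  unique(unlist(strsplit(c(names(mapping$rate_scaled),
                           names(mapping$abundance_set)), "+", fixed = TRUE)))
}

#' Per-gene cohort mean expression
#'
#' Arithmetic mean per gene over all retained cells; the reference population
#' against which single-cell rate multipliers are computed.
#'
#' @param matrix Gene x cell expression matrix (rownames are genes).
#' @param genes Optional subset of genes.
#' @return Named numeric vector of means.
#' @export
cohort_means <- function(matrix, genes = rownames(matrix)) {
  if (is.null(dim(matrix)) || ncol(matrix) < 1)
    stop("expression matrix must contain at least one cell", call. = FALSE)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- Matrix::rowMeans(matrix[genes, , drop = FALSE])
  stats::setNames(as.numeric(m), genes)
}

#' Single-gene rate multiplier
#'
#' Ratio of a cell's expression to the cohort average (the factor
#' `1 + fractional change from the average`), floored at `eps` so dropout
#' zeros yield a small positive rate rather than a degenerate model.
#'
#' @param expr Cell expression (>= 0).
#' @param mean_expr Cohort mean expression (> 0).
#' @param eps Lower floor for the multiplier.
#' @return Dimensionless multiplier.
#' @export
rate_multiplier <- function(expr, mean_expr, eps = 1e-3) {
  if (any(mean_expr <= 0))
    stop("cohort mean expression must be > 0", call. = FALSE)
  pmax(expr / mean_expr, eps)
}

#' Additive two-gene rate multiplier
#'
#' For gene pairs acting on one reaction (G6PD+GLUD1 on NADPH regeneration,
#' PRX1+PRX2 on the peroxiredoxin pool) the expression effect is additive:
#' `(e1 + e2) / (m1 + m2)`, floored at `eps`.
#'
#' @param expr_pair Numeric vector of the cell's expression values.
#' @param mean_pair Matching cohort means (sum > 0).
#' @param eps Lower floor for the multiplier.
#' @return Dimensionless multiplier.
#' @export
additive_multiplier <- function(expr_pair, mean_pair, eps = 1e-3) {
  if (sum(mean_pair) <= 0)
    stop("sum of cohort means must be > 0", call. = FALSE)
  pmax(sum(expr_pair) / sum(mean_pair), eps)
}

group_expression <- function(group, expression) {
  genes <- strsplit(group, "+", fixed = TRUE)[[1]]
  missing <- setdiff(genes, names(expression))
  if (length(missing))
    stop("profile is missing mapped gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  expression[genes]
}

#' Build a per-cell model specification
#'
#' Turns one cell's expression profile into rate-constant multipliers
#' (AQP3, GSR, TXNRD1, NQO1, SOD1, POR, G6PD+GLUD1) and initial-abundance
#' scales (GPX1, CAT, PRX1+PRX2, TXN, GLRX). Rate multipliers are expression
#' ratios to the cohort mean; abundance scales are ratios of equilibrium
#' protein abundances (linear-map fallback for genes without rate constants),
#' so pooled genes with unequal translation/degradation constants are
#' weighted accordingly. A profile at the cohort average yields the identity
#' specification.
#'
#' @param expression Named expression vector covering the mapped genes.
#' @param means Cohort mean expression from [cohort_means()].
#' @param mapping Mapping config from [read_mapping_config()].
#' @param constants Rate-constant table ([read_rate_constants()]).
#' @param linear_maps Linear-map table ([read_linear_maps()]).
#' @param cell_id,patient_id,malignant Optional provenance fields.
#' @return A `cell_model_spec`: multipliers (named by rate constant),
#'   abundance_scale (named by species pool), and provenance.
#' @export
build_cell_model <- function(expression, means, mapping = read_mapping_config(),
                             constants = read_rate_constants(),
                             linear_maps = read_linear_maps(),
                             cell_id = NA_character_,
                             patient_id = NA_character_,
                             malignant = NA) {
  eps <- mapping$multiplier_epsilon %||% 1e-3
  scl <- mapping$expression_scale %||% 1

  mult <- numeric(0)
  for (group in names(mapping$rate_scaled)) {
    e <- group_expression(group, expression)
    m <- group_expression(group, means)
    f <- if (length(e) > 1) additive_multiplier(e, m, eps)
         else rate_multiplier(e, m, eps)
    for (par in unlist(mapping$rate_scaled[[group]]))
      mult[par] <- unname(f)
  }

  scale <- numeric(0)
  for (group in names(mapping$abundance_set)) {
    e <- group_expression(group, expression)
    m <- group_expression(group, means)
    p_cell <- sum(protein_abundances(e, constants, linear_maps, scl))
    p_mean <- sum(protein_abundances(m, constants, linear_maps, scl))
    if (p_mean <= 0)
      stop("cohort-average protein abundance is zero for '", group, "'",
           call. = FALSE)
    scale[mapping$abundance_set[[group]]] <- max(p_cell / p_mean, eps)
  }

  structure(list(cell_id = cell_id, patient_id = patient_id,
                 malignant = malignant, multipliers = mult,
                 abundance_scale = scale, cohort_means = means),
            class = "cell_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a cell specification to a base network and state
#'
#' Multiplies the targeted rate constants and scales the initial
#' concentrations of the abundance-mapped enzyme pools; everything else is
#' inherited from the base model. Dividing the returned parameters by the
#' spec multipliers recovers the base constants exactly.
#'
#' @param network Base `redox_network`.
#' @param spec A `cell_model_spec`.
#' @param state Base initial state (e.g. from [equilibrate_network()]).
#' @param mapping Mapping config providing the species pools.
#' @return List with elements `network` (reparameterized) and `state`.
#' @export
apply_cell_spec <- function(network, spec, state = initial_state(network),
                            mapping = read_mapping_config()) {
  bad <- setdiff(names(spec$multipliers), names(network$params))
  if (length(bad))
    stop("spec targets unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  net <- network
  net$params[names(spec$multipliers)] <-
    net$params[names(spec$multipliers)] * spec$multipliers
  net$compiled <- compile_network(net)

  st <- state
  for (pool in names(spec$abundance_scale)) {
    members <- unlist(mapping$pools[[pool]])
    if (is.null(members))
      stop("mapping declares no species pool '", pool, "'", call. = FALSE)
    st[members] <- st[members] * spec$abundance_scale[[pool]]
  }
  list(network = net, state = st)
}

#' Per-cell molar protein concentrations for the mapped genes
#'
#' Converts each cell's expression of the mapped genes into equilibrium
#' protein copies (linear fallback) and then to molar concentration in the
#' cytosol; the predictor block used by the PLSR analysis.
#'
#' @param matrix Gene x cell expression matrix.
#' @param mapping,constants,linear_maps Configuration tables.
#' @param volume_liters Cytosolic volume used for the molar conversion.
#' @return cells x genes matrix of molar concentrations.
#' @export
protein_concentrations <- function(matrix, mapping = read_mapping_config(),
                                   constants = read_rate_constants(),
                                   linear_maps = read_linear_maps(),
                                   volume_liters = 1e-12) {
  genes <- mapped_genes(mapping)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("matrix is missing mapped gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  scl <- mapping$expression_scale %||% 1
  out <- vapply(genes, function(g) {
    expr <- as.numeric(matrix[g, ]) * scl
    i <- match(g, constants$gene)
    copies <- if (!is.na(i)) {
      protein_equilibrium(expr, constants$k_sp[i], constants$k_dp[i])
    } else {
      j <- match(g, linear_maps$gene)
      if (is.na(j))
        stop("no rate constants or linear map for gene '", g, "'", call. = FALSE)
      protein_linear(expr, linear_maps$slope[j], linear_maps$intercept[j])
    }
    copies_to_molar(copies, volume_liters)
  }, numeric(ncol(matrix)))
  rownames(out) <- colnames(matrix)
  out
}
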