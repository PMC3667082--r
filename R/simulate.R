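#' Configuration of a synthetic signature-concordance study
#'
#' Defines a fully synthetic study mirroring the statistical structure the
#' pipeline analyses: a normal reference group plus latent tumor subtypes
#' with planted up/down marker genes; five inducer profiles sharing a
#' planted core (EMT-like) signature, of which a controlled fraction also
#' marks the first ("mesenchymal-like") subtype; and paired
#' positive/negative sorted samples whose planted (CD133-like) signature
#' opposes the core signature on a controlled fraction of its genes,
#' planting the core-versus-sorted anti-correlation.  The first subtype
#' additionally picks up a fraction of the anti-regulated core genes with
#' the sorted signature's sign, so that the three-way discordance
#' structure is present by construction.
#'
#' @param n_genes total number of genes.
#' @param n_normal normal reference samples in the tumor matrix.
#' @param samples_per_subtype named integer vector, samples per subtype;
#'   the first element is the mesenchymal-like subtype carrying the core
#'   overlap.
#' @param n_inducers number of inducer profiles.
#' @param samples_per_inducer induced samples per inducer.
#' @param n_inducer_controls shared control samples in the inducer matrix.
#' @param n_pairs sorted positive/negative sample pairs.
#' @param effect_size planted shift, log2 units (delta).
#' @param noise_sd i.i.d. Gaussian noise standard deviation (sigma).
#' @param markers_per_subtype planted marker genes per subtype (half up,
#'   half down among the private ones).
#' @param core_signature_size planted core signature size (half up, half
#'   down).
#' @param overlap_fraction rho: fraction of the core also planted, with
#'   the core's sign, as markers of the first subtype.
#' @param anti_fraction fraction of the core whose genes the positive pair
#'   members shift with the opposite sign.
#' @param mes_cd133_fraction fraction of the anti-regulated core genes
#'   (outside the rho overlap) planted in the first subtype with the
#'   sorted signature's sign, opposing the core.
#' @param inducer_private_markers inducer-specific marker genes per
#'   inducer (half up, half down).
#' @param pair_private_markers sorted-signature marker genes outside the
#'   core (half up, half down).
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression is
#'   drawn from Normal(baseline_mean, baseline_sd).
#' @param seed integer seed; the study is a deterministic function of the
#'   configuration.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 5000,
                             n_normal = 10,
                             samples_per_subtype = c(mesenchymal = 30,
                                                     classical = 30,
                                                     neural = 30,
                                                     proneural = 30),
                             n_inducers = 5,
                             samples_per_inducer = 3,
                             n_inducer_controls = 5,
                             n_pairs = 4,
                             effect_size = 2,
                             noise_sd = 0.3,
                             markers_per_subtype = 210,
                             core_signature_size = 200,
                             overlap_fraction = 0.5,
                             anti_fraction = 0.8,
                             mes_cd133_fraction = 0.3,
                             inducer_private_markers = 50,
                             pair_private_markers = 150,
                             baseline_mean = 8,
                             baseline_sd = 1,
                             seed = 1) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$samples_per_subtype))) {
    names(cfg$samples_per_subtype) <-
      paste0("subtype", seq_along(cfg$samples_per_subtype))
  }
  counts <- c(cfg$n_genes, cfg$n_normal, cfg$samples_per_subtype,
              cfg$n_inducers, cfg$samples_per_inducer,
              cfg$n_inducer_controls, cfg$n_pairs,
              cfg$markers_per_subtype, cfg$core_signature_size)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  for (f in c("overlap_fraction", "anti_fraction", "mes_cd133_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]",
                                           call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic signature-concordance study
#'
#' Expression model: gene g has baseline b_g ~ Normal(baseline_mean,
#' baseline_sd) shared by all three matrices; planted effects add or
#' subtract `effect_size` on the log2 scale in the affected samples; every
#' entry receives i.i.d. Normal(0, noise_sd) noise.  The generator is a
#' deterministic function of the configuration: sub-streams for baselines,
#' marker assignment, and each matrix's noise are seeded at fixed offsets
#' from `seed`, so adding a component never perturbs earlier draws.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_study` with elements `expr_tumor`
#'   (normal + subtype samples), `expr_inducers` (induced + control
#'   samples), `expr_pairs` (sorted pairs), `manifests` (list of named
#'   group vectors plus the `pairs` data frame), and `truth` (planted
#'   labels, planted [gene_signature()]s for subtypes / core / sorted
#'   signature / per-inducer profiles, marker bookkeeping and the
#'   configuration).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  subtypes <- names(cfg$samples_per_subtype)
  k <- length(subtypes)

  baseline <- .with_seed(cfg$seed, stats::rnorm(cfg$n_genes,
                                                cfg$baseline_mean,
                                                cfg$baseline_sd))
  names(baseline) <- genes

  plan <- .with_seed(cfg$seed + 1L, .plant_markers(cfg, genes, subtypes))

  delta <- cfg$effect_size
  sgn <- function(set, up) ifelse(set %in% up, delta, -delta)

  ## --- tumor matrix: normals + subtype samples -------------------------
  normal_ids <- sprintf("normal_%02d", seq_len(cfg$n_normal))
  tumor_ids <- unlist(lapply(subtypes, function(s)
    sprintf("%s_%02d", s, seq_len(cfg$samples_per_subtype[[s]]))))
  tumor_labels <- stats::setNames(
    rep(subtypes, times = cfg$samples_per_subtype), tumor_ids)
  expr_tumor <- matrix(baseline, nrow = cfg$n_genes,
                       ncol = cfg$n_normal + length(tumor_ids),
                       dimnames = list(genes, c(normal_ids, tumor_ids)))
  for (s in subtypes) {
    cols <- names(tumor_labels)[tumor_labels == s]
    up <- plan$subtype_up[[s]]; dn <- plan$subtype_down[[s]]
    expr_tumor[up, cols] <- expr_tumor[up, cols] + delta
    expr_tumor[dn, cols] <- expr_tumor[dn, cols] - delta
  }
  expr_tumor <- expr_tumor +
    .with_seed(cfg$seed + 2L,
               matrix(stats::rnorm(length(expr_tumor), 0, cfg$noise_sd),
                      nrow = cfg$n_genes))

  ## --- inducer matrix: induced samples + shared controls ---------------
  inducers <- paste0("inducer", seq_len(cfg$n_inducers))
  ind_ids <- unlist(lapply(inducers, function(i)
    sprintf("%s_%02d", i, seq_len(cfg$samples_per_inducer))))
  ctrl_ids <- sprintf("control_%02d", seq_len(cfg$n_inducer_controls))
  ind_labels <- stats::setNames(
    c(rep(inducers, each = cfg$samples_per_inducer),
      rep("control", cfg$n_inducer_controls)), c(ind_ids, ctrl_ids))
  expr_inducers <- matrix(baseline, nrow = cfg$n_genes,
                          ncol = length(ind_labels),
                          dimnames = list(genes, names(ind_labels)))
  for (i in inducers) {
    cols <- names(ind_labels)[ind_labels == i]
    core_up <- plan$core_up; core_dn <- plan$core_down
    expr_inducers[core_up, cols] <- expr_inducers[core_up, cols] + delta
    expr_inducers[core_dn, cols] <- expr_inducers[core_dn, cols] - delta
    up <- plan$inducer_up[[i]]; dn <- plan$inducer_down[[i]]
    expr_inducers[up, cols] <- expr_inducers[up, cols] + delta
    expr_inducers[dn, cols] <- expr_inducers[dn, cols] - delta
  }
  expr_inducers <- expr_inducers +
    .with_seed(cfg$seed + 3L,
               matrix(stats::rnorm(length(expr_inducers), 0, cfg$noise_sd),
                      nrow = cfg$n_genes))

  ## --- sorted pair matrix ----------------------------------------------
  pair_names <- paste0("pair", seq_len(cfg$n_pairs))
  pairs <- data.frame(pos = paste0(pair_names, "_pos"),
                      neg = paste0(pair_names, "_neg"),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- pair_names
  pair_ids <- c(rbind(pairs$pos, pairs$neg))
  expr_pairs <- matrix(baseline, nrow = cfg$n_genes, ncol = length(pair_ids),
                       dimnames = list(genes, pair_ids))
  sorted_up <- plan$sorted_up; sorted_dn <- plan$sorted_down
  expr_pairs[sorted_up, pairs$pos] <- expr_pairs[sorted_up, pairs$pos] + delta
  expr_pairs[sorted_dn, pairs$pos] <- expr_pairs[sorted_dn, pairs$pos] - delta
  expr_pairs <- expr_pairs +
    .with_seed(cfg$seed + 4L,
               matrix(stats::rnorm(length(expr_pairs), 0, cfg$noise_sd),
                      nrow = cfg$n_genes))

  ## --- planted truth ----------------------------------------------------
  sig <- function(name, up, dn) gene_signature(name, up, dn, genes,
                                               threshold_log2 = max(delta, .Machine$double.eps))
  truth <- list(
    subtype_labels = tumor_labels,
    inducer_labels = ind_labels,
    core_signature = sig("core", plan$core_up, plan$core_down),
    sorted_signature = sig("sorted", plan$sorted_up, plan$sorted_down),
    subtype_signatures = stats::setNames(lapply(subtypes, function(s)
      sig(s, plan$subtype_up[[s]], plan$subtype_down[[s]])), subtypes),
    inducer_signatures = stats::setNames(lapply(inducers, function(i)
      sig(i, union(plan$core_up, plan$inducer_up[[i]]),
          union(plan$core_down, plan$inducer_down[[i]]))), inducers),
    plan = plan,
    config = cfg)

  structure(list(expr_tumor = expr_tumor,
                 expr_inducers = expr_inducers,
                 expr_pairs = expr_pairs,
                 manifests = list(
                   tumor = c(stats::setNames(rep("normal", cfg$n_normal),
                                             normal_ids), tumor_labels),
                   inducers = ind_labels,
                   pairs = pairs),
                 truth = truth),
            class = "synthetic_study")
}

# Draw all planted gene sets.  Core genes split into up/down halves; the
# first subtype receives rho*|core| core genes with the core's sign plus
# mes_cd133_fraction of the remaining anti-regulated core genes with the
# opposite sign; private markers fill every subtype to markers_per_subtype.
.plant_markers <- function(cfg, genes, subtypes) {
  C <- cfg$core_signature_size
  core <- sample(genes, C)
  core_up <- core[seq_len(ceiling(C / 2))]
  core_down <- setdiff(core, core_up)

  anti <- sample(core, round(cfg$anti_fraction * C))

  mes <- subtypes[1]
  s_emt <- sample(core, round(cfg$overlap_fraction * C))
  s_cd <- sample(setdiff(anti, s_emt),
                 round(cfg$mes_cd133_fraction * length(setdiff(anti, s_emt))))

  pool <- setdiff(genes, core)
  draw <- function(n) {
    if (n > length(pool)) stop("marker demands exceed n_genes", call. = FALSE)
    out <- sample(pool, n)
    pool <<- setdiff(pool, out)
    out
  }

  subtype_up <- subtype_down <- stats::setNames(vector("list", length(subtypes)),
                                                subtypes)
  for (s in subtypes) {
    if (s == mes) {
      n_priv <- max(0L, cfg$markers_per_subtype - length(s_emt) - length(s_cd))
      priv <- draw(n_priv)
      priv_up <- priv[seq_len(ceiling(length(priv) / 2))]
      priv_dn <- setdiff(priv, priv_up)
      # core-sign overlap + anti-sign pickup + private fill
      subtype_up[[s]] <- c(intersect(s_emt, core_up),
                           intersect(s_cd, core_down), priv_up)
      subtype_down[[s]] <- c(intersect(s_emt, core_down),
                             intersect(s_cd, core_up), priv_dn)
    } else {
      priv <- draw(cfg$markers_per_subtype)
      subtype_up[[s]] <- priv[seq_len(ceiling(length(priv) / 2))]
      subtype_down[[s]] <- setdiff(priv, subtype_up[[s]])
    }
  }

  inducers <- paste0("inducer", seq_len(cfg$n_inducers))
  inducer_up <- inducer_down <- stats::setNames(vector("list", length(inducers)),
                                                inducers)
  for (i in inducers) {
    priv <- draw(cfg$inducer_private_markers)
    inducer_up[[i]] <- priv[seq_len(ceiling(length(priv) / 2))]
    inducer_down[[i]] <- setdiff(priv, inducer_up[[i]])
  }

  pair_priv <- draw(cfg$pair_private_markers)
  pair_priv_up <- pair_priv[seq_len(ceiling(length(pair_priv) / 2))]
  pair_priv_dn <- setdiff(pair_priv, pair_priv_up)

  list(core_up = sort(core_up), core_down = sort(core_down),
       anti = sort(anti), s_emt = sort(s_emt), s_cd = sort(s_cd),
       subtype_up = lapply(subtype_up, sort),
       subtype_down = lapply(subtype_down, sort),
       inducer_up = lapply(inducer_up, sort),
       inducer_down = lapply(inducer_down, sort),
       # sorted (CD133-like): anti-core genes flipped + private markers
       sorted_up = sort(c(intersect(anti, core_down), pair_priv_up)),
       sorted_down = sort(c(intersect(anti, core_up), pair_priv_dn)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("synthetic_study: %d genes; tumor %d normal + %d subtype",
                     " samples (%d subtypes); %d inducers; %d sorted pairs\n"),
              cfg$n_genes, cfg$n_normal, length(x$truth$subtype_labels),
              length(cfg$samples_per_subtype), cfg$n_inducers, cfg$n_pairs))
  invisible(x)
}

#' Serialize a study's planted ground truth to JSON
#'
#' Emits the planted labels, signature gene sets and configuration so that
#' a test harness can audit any derived result against the truth.
#'
#' @param study a [generate_study()] result.
#' @param path optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
truth_report <- function(study, path = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  tr <- study$truth
  sig_obj <- function(s) list(name = s$name, up = s$up, down = s$down,
                              n_universe = length(s$universe))
  obj <- list(
    subtype_labels = as.list(tr$subtype_labels),
    core_signature = sig_obj(tr$core_signature),
    sorted_signature = sig_obj(tr$sorted_signature),
    subtype_signatures = lapply(tr$subtype_signatures, sig_obj),
    inducer_signatures = lapply(tr$inducer_signatures, sig_obj),
    config = unclass(tr$config))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Write a study's matrices and manifests in the package's text formats
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(study$expr_tumor, file.path(dir, "expr_tumor.tsv"))
  write_expression_table(study$expr_inducers,
                         file.path(dir, "expr_inducers.tsv"))
  write_expression_table(study$expr_pairs, file.path(dir, "expr_pairs.tsv"))
  write_sample_manifest(study$manifests$tumor,
                        file.path(dir, "manifest_tumor.tsv"))
  write_sample_manifest(study$manifests$inducers,
                        file.path(dir, "manifest_inducers.tsv"))
  utils::write.table(study$manifests$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_report(study, file.path(dir, "truth.json"))
  invisible(dir)
}
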