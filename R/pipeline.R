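# End-to-end orchestration of the two-tissue analysis: DE screen -> PPI
# score filter -> DEG-seeded subnetwork -> co-expression modules ->
# risk-list enrichment and dysfunctional flags -> pivot regulators ->
# tissue-specific modules -> cross-tissue crosstalk. Stages exchange plain
# TSV/GMT files; one root seed feeds named substreams.

#' Build a pipeline configuration
#'
#' @param tissues character vector of tissue names (crosstalk requires
#'   exactly two).
#' @param counts,metadata named character vectors (per tissue) of input file
#'   paths.
#' @param network path to the PPI edge-list TSV.
#' @param sfari,dvmt paths to risk-gene list files.
#' @param tissue_genes path to the tissue-specific gene list.
#' @param regulators path to the regulator-target GMT.
#' @param powers named numeric vector of per-tissue soft-threshold powers
#'   (reference design: 12 for the corpus-callosum cohort, 8 for the
#'   prefrontal-cortex cohort).
#' @param fc_threshold,p_threshold DEG thresholds.
#' @param min_score inclusive combined-score threshold for the PPI filter.
#' @param min_module_size,cut_height,merge_height,hub_threshold module
#'   detection parameters.
#' @param max_module_size strict size cap for candidate modules.
#' @param alpha significance level for enrichment/pivot/crosstalk flags.
#' @param n_perm permutation draws per crosstalk pair.
#' @param seed root seed.
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tissues, counts, metadata, network, sfari, dvmt,
                            tissue_genes, regulators,
                            powers = c(CC = 12, PFC = 8),
                            fc_threshold = 1.2, p_threshold = 0.05,
                            min_score = 900L, min_module_size = 20L,
                            cut_height = 0.99, merge_height = 0.15,
                            hub_threshold = 0.8, max_module_size = 500L,
                            alpha = 0.05, n_perm = 100000L, seed = 1L,
                            out_dir = "coexcross_out") {
  cfg <- list(tissues = tissues, counts = counts, metadata = metadata,
              network = network, sfari = sfari, dvmt = dvmt,
              tissue_genes = tissue_genes, regulators = regulators,
              powers = powers, fc_threshold = fc_threshold,
              p_threshold = p_threshold, min_score = as.integer(min_score),
              min_module_size = as.integer(min_module_size),
              cut_height = cut_height, merge_height = merge_height,
              hub_threshold = hub_threshold,
              max_module_size = as.integer(max_module_size), alpha = alpha,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  stopifnot(all(tissues %in% names(counts)), all(tissues %in% names(metadata)),
            all(tissues %in% names(powers)), all(powers[tissues] >= 1),
            is.numeric(seed))
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Expected layout: top-level scalar options matching the
#' [pipeline_config()] arguments, with `counts`, `metadata` and `powers`
#' given as per-tissue mappings. Relative paths are resolved against the
#' YAML file's directory.
#'
#' @param path path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  tissues <- y$tissues %||% names(y$counts)
  args <- list(
    tissues = tissues,
    counts = vapply(y$counts, resolve, character(1))[tissues],
    metadata = vapply(y$metadata, resolve, character(1))[tissues],
    network = resolve(y$network), sfari = resolve(y$sfari),
    dvmt = resolve(y$dvmt), tissue_genes = resolve(y$tissue_genes),
    regulators = resolve(y$regulators))
  for (nm in c("fc_threshold", "p_threshold", "min_score", "min_module_size",
               "cut_height", "merge_height", "hub_threshold",
               "max_module_size", "alpha", "n_perm", "seed", "out_dir")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$powers)) args$powers <- unlist(y$powers)
  do.call(pipeline_config, args)
}

#' Validate pipeline inputs before running
#'
#' Checks that every referenced file exists and parses in its expected
#' dialect (column names, GMT well-formedness), and that gene symbols
#' overlap across the expression matrices, the network, and the gene lists.
#' Expression genes disjoint from network nodes is a hard error; overlap
#' below 50% passes with a warning.
#'
#' @param config a `pipeline_config`.
#' @param verbose emit log messages.
#' @return A list report with per-file status and overlap fractions.
#' @export
validate_inputs <- function(config, verbose = TRUE) {
  files <- c(unlist(config$counts), unlist(config$metadata), config$network,
             config$sfari, config$dvmt, config$tissue_genes,
             config$regulators)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  report <- list(files = files, overlap = list())
  net <- read_edges(config$network)
  nodes <- igraph::V(net)$name
  for (ts in config$tissues) {
    counts <- read_counts(config$counts[[ts]])
    meta <- read_metadata(config$metadata[[ts]])
    if (!all(colnames(counts) %in% meta$sample_id)) {
      stop("samples in ", config$counts[[ts]],
           " are missing from its metadata")
    }
    ov <- mean(rownames(counts) %in% nodes)
    report$overlap[[ts]] <- ov
    if (ov == 0) {
      stop("expression genes of tissue ", ts,
           " are disjoint from the network nodes")
    }
    if (ov < 0.5) {
      warning("only ", round(100 * ov), "% of tissue ", ts,
              " genes are network nodes")
    }
  }
  read_gmt(config$regulators)
  for (f in c(config$sfari, config$dvmt, config$tissue_genes)) {
    if (length(read_gene_list(f)) == 0L) stop("empty gene list: ", f)
  }
  cx_log("validate_inputs: all inputs readable", verbose = verbose)
  invisible(report)
}

#' Run the full two-tissue analysis
#'
#' Executes, per tissue: DE screen, DEG extraction, score-filtered PPI
#' subnetwork seeded by the DEGs, co-expression module detection on the
#' subnetwork genes, candidate-module selection, SFARI/DVMT enrichment with
#' dysfunctional flags, and pivot-regulator detection; then cross-tissue
#' module crosstalk between the two tissues' tissue-specific modules. All
#' stage outputs are written as TSV with `#` parameter headers, plus a JSON
#' run manifest with per-file checksums.
#'
#' @param config a `pipeline_config`.
#' @param verbose emit log messages.
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config, verbose = TRUE) {
  t0 <- Sys.time()
  validate_inputs(config, verbose = verbose)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  seeds <- list()
  emit <- function(df, name, comments) {
    p <- file.path(config$out_dir, name)
    write_tsv(df, p, comments)
    outputs <<- c(outputs, p)
    p
  }

  net_full <- read_edges(config$network)
  net <- filter_by_score(net_full, config$min_score)
  cx_log("network: ", igraph::vcount(net), " nodes / ", igraph::ecount(net),
         " edges at combined score >= ", config$min_score, verbose = verbose)

  per_tissue <- list()
  for (ts in config$tissues) {
    counts <- read_counts(config$counts[[ts]])
    meta <- read_metadata(config$metadata[[ts]])
    meta <- meta[match(colnames(counts), meta$sample_id), ]

    de <- de_test(counts, meta$condition,
                  fc_threshold = config$fc_threshold,
                  p_threshold = config$p_threshold)
    degs <- filter_degs(de, config$fc_threshold, config$p_threshold)
    emit(de, paste0("de_", ts, ".tsv"),
         c(paste0("tissue: ", ts),
           paste0("fc_threshold: ", config$fc_threshold,
                  "; p_threshold: ", config$p_threshold,
                  "; pseudo_count: 0.5")))
    cx_log("DE ", ts, ": ", length(degs), " DEGs of ", nrow(counts),
           " genes", verbose = verbose)

    sub <- seed_subnetwork(net, degs, verbose = verbose)
    gene_set <- intersect(igraph::V(sub)$name, rownames(counts))
    if (length(gene_set) < config$min_module_size) {
      stop("stage coexpr(", ts, "): subnetwork gene set too small")
    }
    expr <- expression_transform(counts[gene_set, , drop = FALSE],
                                 verbose = verbose)
    mods <- detect_modules(expr, power = config$powers[[ts]],
                           min_module_size = config$min_module_size,
                           cut_height = config$cut_height,
                           merge_height = config$merge_height,
                           hub_threshold = config$hub_threshold)
    emit(mods$kme, paste0("modules_", ts, ".tsv"),
         c(paste0("tissue: ", ts),
           paste0("power: ", config$powers[[ts]],
                  "; min_module_size: ", config$min_module_size,
                  "; cut_height: ", config$cut_height,
                  "; merge_height: ", config$merge_height,
                  "; hub_threshold: ", config$hub_threshold)))
    if (!is.null(mods$eigengenes)) {
      emit(data.frame(sample_id = rownames(mods$eigengenes),
                      mods$eigengenes, check.names = FALSE),
           paste0("eigengenes_", ts, ".tsv"), paste0("tissue: ", ts))
    }
    n_mod <- length(unique(mods$assignment[mods$assignment > 0]))
    cx_log("modules ", ts, ": ", n_mod, " modules over ",
           length(gene_set), " genes", verbose = verbose)

    universe <- rownames(expr)
    assign <- mods$assignment
    candidates <- select_candidate_modules(assign, degs,
                                           config$max_module_size)
    sfari <- read_gene_list(config$sfari)
    dvmt <- read_gene_list(config$dvmt)
    cand_assign <- assign
    cand_assign[!(cand_assign %in% candidates)] <- 0L
    en_s <- module_list_enrichment(cand_assign, sfari, universe)
    en_d <- module_list_enrichment(cand_assign, dvmt, universe)
    dys <- flag_dysfunctional(en_s, en_d, config$alpha)
    emit(en_s, paste0("enrichment_sfari_", ts, ".tsv"),
         paste0("tissue: ", ts, "; universe: coexpression gene set"))
    emit(en_d, paste0("enrichment_dvmt_", ts, ".tsv"),
         paste0("tissue: ", ts, "; universe: coexpression gene set"))
    emit(dys, paste0("dysfunctional_", ts, ".tsv"),
         paste0("tissue: ", ts, "; alpha: ", config$alpha))

    regmap <- read_gmt(config$regulators)
    piv <- pivot_regulators(regmap, assign, candidates, universe,
                            alpha = config$alpha)
    emit(piv, paste0("pivots_", ts, ".tsv"),
         paste0("tissue: ", ts, "; alpha: ", config$alpha,
                "; min in-module targets: 2"))

    per_tissue[[ts]] <- list(degs = degs, assign = assign,
                             candidates = candidates, dysfunctional = dys,
                             universe = universe)
  }

  if (length(config$tissues) == 2L) {
    tg <- read_gene_list(config$tissue_genes)
    ts_mods <- lapply(config$tissues, function(ts) {
      pt <- per_tissue[[ts]]
      sel <- tissue_specific_modules(pt$assign, pt$degs, tg, pt$candidates)
      sets <- lapply(sel, function(m) names(pt$assign)[pt$assign == m])
      names(sets) <- paste0(ts, "_M", sel)
      sets
    })
    names(ts_mods) <- config$tissues
    if (all(lengths(ts_mods) > 0)) {
      ct_seed <- substream_seed(config$seed, "crosstalk")
      seeds$crosstalk <- ct_seed
      ct <- all_pairs_crosstalk(net, ts_mods[[1]], ts_mods[[2]],
                                n_perm = config$n_perm, seed = ct_seed,
                                alpha = config$alpha)
      emit(ct, "crosstalk.tsv",
           c(paste0("n_perm: ", config$n_perm, "; alpha: ", config$alpha,
                    "; sampling frame: score-filtered network nodes"),
             paste0("root seed: ", config$seed)))
      cx_log("crosstalk: ", nrow(ct), " pairs tested, ",
             sum(ct$significant), " significant", verbose = verbose)
    } else {
      cx_log("crosstalk skipped: no tissue-specific module in at least ",
             "one tissue", verbose = verbose)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("coexcross")),
    config = unclass(config),
    seeds = seeds,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
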