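#' Differential-expression simulation specification
#'
#' Synthetic DE table: null genes carry p ~ Uniform(0,1) and log2
#' fold-changes symmetric around 0; "true" genes (free-standing or members
#' of planted gene sets) carry small p-values (log-uniform in
#' `true_p_range`, chosen well below the expected minimum of the null
#' p-values so that planted genes rank above all nulls by construction)
#' and signed fold-changes drawn from N(effect mean, effect sd) in the
#' planted direction.
#'
#' @param n_genes Gene universe size.
#' @param n_true_up,n_true_down Free-standing true genes per direction
#'   (in addition to planted set members).
#' @param effect_log2fc `c(mean, sd)` of the absolute log2 fold-change for
#'   true genes.
#' @param true_p_range Range for true-gene p-values (log-uniform).
#' @param null_log2fc_sd Spread of null fold-changes around 0.
#' @param planted_sets Named list; each element a list with `genes`
#'   (character, subset of the universe) and `direction` (+1 or -1).
#' @param seed Integer seed.
#' @return An object of class `de_sim_spec`.
#' @export
de_sim_spec <- function(n_genes = 10000, n_true_up = 100, n_true_down = 100,
                        effect_log2fc = c(1.5, 0.3),
                        true_p_range = c(1e-10, 1e-6),
                        null_log2fc_sd = 0.2,
                        planted_sets = list(), seed = 1L) {
  check_scalar_pos(n_genes, "n_genes")
  if (n_true_up < 0 || n_true_down < 0)
    stop_field("n_true_up", "true-gene counts must be >= 0")
  if (n_true_up + n_true_down > n_genes)
    stop_field("n_true_up", "n_true_up + n_true_down must be <= n_genes")
  universe <- sprintf("G%05d", seq_len(n_genes))
  for (nm in names(planted_sets)) {
    s <- planted_sets[[nm]]
    if (!all(s$genes %in% universe))
      stop_field(sprintf("planted_sets$%s", nm), "members must be within the gene universe")
    if (!s$direction %in% c(-1, 1))
      stop_field(sprintf("planted_sets$%s", nm), "direction must be +1 or -1")
  }
  structure(list(n_genes = as.integer(n_genes), n_true_up = as.integer(n_true_up),
                 n_true_down = as.integer(n_true_down),
                 effect_log2fc = effect_log2fc, true_p_range = true_p_range,
                 null_log2fc_sd = null_log2fc_sd,
                 planted_sets = planted_sets, universe = universe,
                 seed = as.integer(seed)),
            class = "de_sim_spec")
}

#' Generate a synthetic DE table with planted-set ground truth
#'
#' @param spec A [de_sim_spec()].
#' @return List with `de` (data frame: `gene`, `pval`, `log2fc`), `truth`
#'   (data frame: `gene`, `is_true`, `direction`), `planted_sets`, `spec`.
#' @export
gen_de_table <- function(spec) {
  stopifnot(inherits(spec, "de_sim_spec"))
  set.seed(spec$seed)
  genes <- spec$universe
  n <- spec$n_genes
  pval <- runif(n)
  log2fc <- rnorm(n, 0, spec$null_log2fc_sd)
  direction <- rep(0L, n)

  planted_members <- unique(unlist(lapply(spec$planted_sets, `[[`, "genes")))
  free <- setdiff(genes, planted_members)
  true_up <- sample(free, spec$n_true_up)
  true_down <- sample(setdiff(free, true_up), spec$n_true_down)

  assign_true <- function(sel, dirn) {
    idx <- match(sel, genes)
    lp <- runif(length(idx), log10(spec$true_p_range[1]), log10(spec$true_p_range[2]))
    pval[idx] <<- 10^lp
    log2fc[idx] <<- dirn * abs(rnorm(length(idx), spec$effect_log2fc[1], spec$effect_log2fc[2]))
    direction[idx] <<- dirn
  }
  assign_true(true_up, 1L)
  assign_true(true_down, -1L)
  for (s in spec$planted_sets) assign_true(s$genes, s$direction)

  list(de = data.frame(gene = genes, pval = pval, log2fc = log2fc,
                       stringsAsFactors = FALSE),
       truth = data.frame(gene = genes, is_true = direction != 0,
                          direction = direction, stringsAsFactors = FALSE),
       planted_sets = spec$planted_sets,
       spec = spec)
}

#' Write a DE table as TSV (gene, pval, log2fc)
#'
#' @param de Data frame with columns `gene`, `pval`, `log2fc`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de[, c("gene", "pval", "log2fc")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE TSV (gene, pval, log2fc)
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_de_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, members; tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) next
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
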