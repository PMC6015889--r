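DEFAULT_CODE_MAP <- c(`2` = "QQ", `1` = "Qq", `0` = "qq")

#' Read a genotype matrix
#'
#' Two dialects are supported.  `matrix-csv`: a CSV with a `line` column,
#' an optional `family` column, and one column per marker holding coded
#' calls (default coding 2 = QQ, 1 = Qq, 0 = qq, empty/NA = missing).
#' `hapmap-like`: a tab-separated file with columns `rs`, `alleles`
#' (e.g. `A/G`, first allele = non-B73 `Q`, second = B73 `q`), `chrom`,
#' `pos`, then one column per line holding two-letter allele calls
#' (`NN` or `--` = missing).
#'
#' @param path file path.
#' @param dialect `"matrix-csv"` or `"hapmap-like"`.
#' @param code_map named character vector mapping matrix-csv cell codes to
#'   genotype codes.
#' @return [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("matrix-csv", "hapmap-like"),
                           code_map = DEFAULT_CODE_MAP) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "matrix-csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!"line" %in% names(df)) stop("matrix-csv needs a 'line' column")
    fam <- NULL
    if ("family" %in% names(df)) {
      fam <- stats::setNames(df$family, df$line)
      df$family <- NULL
    }
    mk <- names(df)[names(df) != "line"]
    if (anyDuplicated(mk)) {
      stop("duplicate marker id in header: ", mk[duplicated(mk)][1L])
    }
    calls <- as.matrix(df[mk])
    rownames(calls) <- df$line
    dec <- function(v) {
      out <- rep(NA_character_, length(v))
      blank <- is.na(v) | v == "" | v == "NA"
      out[blank] <- "MISSING"
      hit <- !blank & v %in% names(code_map)
      out[hit] <- code_map[v[hit]]
      bad <- which(is.na(out))
      if (length(bad)) {
        stop("unparseable genotype cell '", v[bad[1L]], "'")
      }
      out
    }
    for (j in seq_len(ncol(calls))) {
      cell <- tryCatch(dec(calls[, j]), error = function(e) {
        stop("column ", mk[j], ": ", conditionMessage(e), call. = FALSE)
      })
      calls[, j] <- cell
    }
    genotype_matrix(calls, fam)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("rs", "alleles", "chrom", "pos")
    if (!all(need %in% names(df))) stop("hapmap-like needs columns: ",
                                        paste(need, collapse = ", "))
    lines <- setdiff(names(df), need)
    if (!length(lines)) stop("hapmap-like file has no line columns")
    al <- strsplit(df$alleles, "/", fixed = TRUE)
    if (any(lengths(al) != 2L)) stop("malformed alleles field")
    calls <- matrix(NA_character_, length(lines), nrow(df),
                    dimnames = list(lines, df$rs))
    for (i in seq_len(nrow(df))) {
      Q <- al[[i]][1L]; q <- al[[i]][2L]
      v <- as.character(df[i, lines])
      out <- rep(NA_character_, length(v))
      out[v %in% c("NN", "--", "", NA)] <- "MISSING"
      out[v == paste0(Q, Q)] <- "QQ"
      out[v == paste0(q, q)] <- "qq"
      out[v %in% c(paste0(Q, q), paste0(q, Q))] <- "Qq"
      bad <- which(is.na(out))
      if (length(bad)) stop("row ", df$rs[i], ", line ", lines[bad[1L]],
                            ": unparseable call '", v[bad[1L]], "'")
      calls[, i] <- out
    }
    if (anyDuplicated(df$rs)) stop("duplicate marker id: ",
                                   df$rs[duplicated(df$rs)][1L])
    genotype_matrix(calls)
  }
}

#' Write a genotype matrix as matrix-csv
#'
#' @param gm [genotype_matrix()].
#' @param path output path.
#' @param code_map coding used for cells (inverse of the read mapping);
#'   missing calls are written as empty cells.
#' @export
write_genotypes <- function(gm, path, code_map = DEFAULT_CODE_MAP) {
  stopifnot(inherits(gm, "genotype_matrix"))
  inv <- stats::setNames(names(code_map), code_map)
  enc <- matrix(inv[gm$calls], nrow(gm$calls), ncol(gm$calls),
                dimnames = dimnames(gm$calls))
  enc[gm$calls == "MISSING"] <- ""
  df <- data.frame(line = rownames(enc), family = unname(gm$family),
                   enc, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' CSV with header `line,env,trait,value`.
#'
#' @param path file path.
#' @param gm optional [genotype_matrix()]; when supplied (strict mode) every
#'   phenotyped line must be genotyped.
#' @return [phenotype_table()].
#' @export
read_phenotypes <- function(path, gm = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "env", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype file needs header columns: ", paste(need, collapse = ","))
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    if (anyNA(v) && !anyNA(df$value)) stop("non-numeric phenotype value: '",
                                           df$value[which(is.na(v))[1L]], "'")
    df$value <- v
  }
  phenotype_table(df, gm)
}

#' Write a phenotype table
#' @param ph [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.csv(as.data.frame(ph), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

EFFECT_KINDS <- c(FIXED_KINDS, RANDOM_KINDS)
EFFECTS_HEADER <- c("qts1", "qts2", "kind", "env", "estimate", "se",
                    "neg_log10_p_ew", "pve_pct")

#' Serialize a genetic architecture as an effects table
#'
#' One row per nonzero effect, in the same layout the estimation stage
#' reports (`qts1`, `qts2`, `kind`, `env`, `estimate`, ...), so a simulated
#' truth can be written, read back and scored against estimates.
#'
#' @param arch [genetic_architecture()].
#' @return data.frame in effects-table layout (se / p / pve columns `NA`).
#' @export
architecture_to_effects <- function(arch) {
  rows <- list()
  add <- function(q1, q2, kind, env, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      qts1 = q1, qts2 = q2, kind = kind, env = env, estimate = est,
      se = NA_real_, neg_log10_p_ew = NA_real_, pve_pct = NA_real_,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(arch$loci))) {
    l <- arch$loci[k, ]
    if (l$a != 0) add(l$marker, NA_character_, "a", NA_integer_, l$a)
    if (l$d != 0) add(l$marker, NA_character_, "d", NA_integer_, l$d)
  }
  for (k in seq_len(nrow(arch$pairs))) {
    p <- arch$pairs[k, ]
    for (kind in c("aa", "ad", "da", "dd")) {
      if (p[[kind]] != 0) add(p$marker1, p$marker2, kind, NA_integer_, p[[kind]])
    }
  }
  for (k in seq_len(nrow(arch$env_loci))) {
    l <- arch$env_loci[k, ]
    if (l$ae != 0) add(l$marker, NA_character_, "ae", l$env, l$ae)
    if (l$de != 0) add(l$marker, NA_character_, "de", l$env, l$de)
  }
  for (k in seq_len(nrow(arch$env_pairs))) {
    p <- arch$env_pairs[k, ]
    for (kind in c("aae", "ade", "dae", "dde")) {
      if (p[[kind]] != 0) add(p$marker1, p$marker2, kind, p$env, p[[kind]])
    }
  }
  if (!length(rows)) {
    return(data.frame(qts1 = character(), qts2 = character(), kind = character(),
                      env = integer(), estimate = numeric(), se = numeric(),
                      neg_log10_p_ew = numeric(), pve_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Rebuild a genetic architecture from an effects table
#'
#' @param eff effects-table data.frame (as written by
#'   [architecture_to_effects()] or the estimation stage).
#' @param mu population mean (not carried by the effects table).
#' @param residual_sd residual standard deviation.
#' @return [genetic_architecture()].
#' @export
effects_to_architecture <- function(eff, mu = 0, residual_sd = 1) {
  bad <- setdiff(eff$kind, EFFECT_KINDS)
  if (length(bad)) stop("unknown effect kind(s): ", paste(bad, collapse = ", "))
  env_kinds <- eff$kind %in% RANDOM_KINDS
  if (any(env_kinds & is.na(eff$env))) stop("environment-interaction effect without env index")
  loci <- list(); pairs <- list(); env_loci <- list(); env_pairs <- list()
  for (k in seq_len(nrow(eff))) {
    r <- eff[k, ]
    if (r$kind %in% c("a", "d")) {
      row <- data.frame(marker = r$qts1, a = 0, d = 0)
      row[[r$kind]] <- r$estimate
      loci[[length(loci) + 1L]] <- row
    } else if (r$kind %in% c("aa", "ad", "da", "dd")) {
      row <- data.frame(marker1 = r$qts1, marker2 = r$qts2,
                        aa = 0, ad = 0, da = 0, dd = 0)
      row[[r$kind]] <- r$estimate
      pairs[[length(pairs) + 1L]] <- row
    } else if (r$kind %in% c("ae", "de")) {
      row <- data.frame(marker = r$qts1, env = r$env, ae = 0, de = 0)
      row[[r$kind]] <- r$estimate
      env_loci[[length(env_loci) + 1L]] <- row
    } else {
      row <- data.frame(marker1 = r$qts1, marker2 = r$qts2, env = r$env,
                        aae = 0, ade = 0, dae = 0, dde = 0)
      row[[r$kind]] <- r$estimate
      env_pairs[[length(env_pairs) + 1L]] <- row
    }
  }
  agg <- function(lst, empty, keys, vals) {
    if (!length(lst)) return(empty)
    df <- do.call(rbind, lst)
    stats::aggregate(df[vals], df[keys], FUN = sum)
  }
  genetic_architecture(
    mu = mu,
    loci = agg(loci, data.frame(marker = character(), a = numeric(), d = numeric()),
               "marker", c("a", "d")),
    pairs = agg(pairs, data.frame(marker1 = character(), marker2 = character(),
                                  aa = numeric(), ad = numeric(),
                                  da = numeric(), dd = numeric()),
                c("marker1", "marker2"), c("aa", "ad", "da", "dd")),
    env_loci = agg(env_loci, empty_env_loci(), c("marker", "env"), c("ae", "de")),
    env_pairs = agg(env_pairs, empty_env_pairs(), c("marker1", "marker2", "env"),
                    c("aae", "ade", "dae", "dde")),
    residual_sd = residual_sd)
}

#' Write an effects table (TSV)
#' @param eff effects-table data.frame.
#' @param path output path.
#' @export
write_effects_table <- function(eff, path) {
  stopifnot(all(EFFECTS_HEADER %in% names(eff)))
  utils::write.table(eff[EFFECTS_HEADER], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an effects table (TSV)
#' @param path file path.
#' @return data.frame in effects-table layout.
#' @export
read_effects_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df), EFFECTS_HEADER)) {
    stop("unexpected effects-table header: ", paste(names(df), collapse = ","))
  }
  df$qts2 <- as.character(df$qts2)
  df$qts1 <- as.character(df$qts1)
  df
}

HERITABILITY_HEADER <- c("trait", "hA2", "hD2", "hAA2", "hAD2", "hDA2", "hDD2",
                         "hAE2", "hDE2", "hAAE2", "hT2", "hDp2")

#' Write a heritability table (TSV, one row per trait)
#' @param her data.frame with the heritability-table columns.
#' @param path output path.
#' @export
write_heritability_table <- function(her, path) {
  stopifnot(all(HERITABILITY_HEADER %in% names(her)))
  utils::write.table(her[HERITABILITY_HEADER], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotypic-value prediction table (TSV)
#'
#' Rows `QQ`, `qq`, `F1`, `Best line`, `Superior line`, `Superior hybrid`;
#' columns `entry`, `G`, `G_GE1` ... `G_GE{E}`.
#'
#' @param pred prediction data.frame as produced by [plan_report()].
#' @param path output path.
#' @export
write_prediction_table <- function(pred, path) {
  utils::write.table(pred, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an epistasis edge list from an effects table
#'
#' One edge per QTS pair carrying any epistasis effect; the reported kind and
#' estimate are those of the largest-magnitude general epistasis effect (or,
#' if the pair has only environment-specific effects, the largest of those).
#' The significance class records whether the pair carries general effects,
#' environment-specific effects, or both.
#'
#' @param eff effects-table data.frame.
#' @return data.frame with columns `qts1`, `qts2`, `kind`, `estimate`,
#'   `class`.
#' @export
epistasis_edge_list <- function(eff) {
  ep <- eff[eff$kind %in% c("aa", "ad", "da", "dd", "aae", "ade", "dae", "dde"), ,
            drop = FALSE]
  if (!nrow(ep)) {
    return(data.frame(qts1 = character(), qts2 = character(), kind = character(),
                      estimate = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(ep$qts1, ep$qts2)
  out <- lapply(split(ep, key), function(g) {
    gen <- g[g$kind %in% c("aa", "ad", "da", "dd"), , drop = FALSE]
    env <- g[!(g$kind %in% c("aa", "ad", "da", "dd")), , drop = FALSE]
    cls <- if (nrow(gen) && nrow(env)) "both" else if (nrow(gen)) "general" else "environment-specific"
    top <- if (nrow(gen)) gen[which.max(abs(gen$estimate)), ] else env[which.max(abs(env$estimate)), ]
    data.frame(qts1 = top$qts1, qts2 = top$qts2, kind = top$kind,
               estimate = top$estimate, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  ord <- order(parse_marker_id(out$qts1)$chrom, parse_marker_id(out$qts1)$pos,
               parse_marker_id(out$qts2)$chrom, parse_marker_id(out$qts2)$pos)
  out[ord, , drop = FALSE]
}

#' Write all analysis reports to a directory
#'
#' Emits whichever of the four standard TSVs the `results` list carries:
#' `effects` (effects table), `heritability` (one row per trait),
#' `prediction` (genotypic-value table) and `edges` (epistasis edge list;
#' derived from `effects` when absent).
#'
#' @param results named list with any of `effects`, `heritability`,
#'   `prediction`, `edges`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(results$effects)) {
    eff <- results$effects
    # stable ordering: marker order, then kind
    ord <- order(parse_marker_id(eff$qts1)$chrom, parse_marker_id(eff$qts1)$pos,
                 match(eff$kind, EFFECT_KINDS), eff$env, na.last = TRUE)
    eff <- eff[ord, , drop = FALSE]
    p <- file.path(dir, "effects.tsv")
    write_effects_table(eff, p); written <- c(written, p)
    edges <- if (is.null(results$edges)) epistasis_edge_list(eff) else results$edges
    p <- file.path(dir, "epistasis_edges.tsv")
    utils::write.table(edges, p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  } else if (!is.null(results$edges)) {
    p <- file.path(dir, "epistasis_edges.tsv")
    utils::write.table(results$edges, p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  if (!is.null(results$heritability)) {
    p <- file.path(dir, "heritability.tsv")
    write_heritability_table(results$heritability, p); written <- c(written, p)
  }
  if (!is.null(results$prediction)) {
    p <- file.path(dir, "prediction.tsv")
    write_prediction_table(results$prediction, p); written <- c(written, p)
  }
  invisible(written)
}
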