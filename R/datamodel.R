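GENO_CODES <- c("QQ", "Qq", "qq", "MISSING")

#' Parse marker identifiers of the form "S{chrom}_{pos}"
#'
#' Marker IDs follow the convention used for maize NAM SNPs: `S` followed by
#' the chromosome number, an underscore, and the 1-based physical position in
#' base pairs (e.g. `S1_35133062`).
#'
#' @param id character vector of marker IDs.
#' @return data.frame with columns `id`, `chrom`, `pos`.
#' @export
#' @examples
#' parse_marker_id("S1_35133062")
parse_marker_id <- function(id) {
  ok <- grepl("^S[0-9]+_[0-9]+$", id)
  if (!all(ok)) {
    stop("malformed marker id(s): ", paste(utils::head(id[!ok], 5L), collapse = ", "))
  }
  body <- sub("^S", "", id)
  parts <- strsplit(body, "_", fixed = TRUE)
  chrom <- vapply(parts, function(p) as.integer(p[[1L]]), integer(1))
  pos <- vapply(parts, function(p) as.numeric(p[[2L]]), numeric(1))
  if (any(chrom < 1L) || any(pos < 1)) stop("marker chrom/pos must be positive")
  data.frame(id = id, chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Compose a marker identifier
#' @param chrom,pos positive integers.
#' @return character vector "S{chrom}_{pos}".
#' @export
marker_id <- function(chrom, pos) sprintf("S%d_%d", as.integer(chrom), as.integer(pos))

#' Construct a genotype matrix
#'
#' The container for biallelic genotype calls of inbred-line panels: one row
#' per line, one column per marker, calls in `{"QQ", "Qq", "qq", "MISSING"}`
#' (`NA` is accepted as an alias for `"MISSING"`).  `Q` denotes the non-common
#' (founder) allele and `q` the common-parent (B73) allele.
#'
#' @param calls character matrix, lines x markers, with rownames (line IDs)
#'   and colnames (marker IDs of the form `S{chrom}_{pos}`).
#' @param family named character vector mapping line ID to family label.  If
#'   `NULL`, families are parsed from line IDs of the form `Z{family}E{line}`
#'   (e.g. `Z019E0033` belongs to family `Z019`); lines not matching that
#'   pattern fall into family `"F1"`.
#' @return object of class `genotype_matrix` with elements `calls`, `family`,
#'   `markers` (data.frame id/chrom/pos).
#' @export
genotype_matrix <- function(calls, family = NULL) {
  if (!is.matrix(calls) || !is.character(calls)) stop("`calls` must be a character matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` needs rownames (lines) and colnames (marker ids)")
  }
  if (anyDuplicated(rownames(calls))) stop("duplicate line IDs")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker IDs")
  calls[is.na(calls)] <- "MISSING"
  bad <- !(calls %in% GENO_CODES)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop("unknown genotype code '", calls[idx], "' at line ",
         rownames(calls)[(idx - 1L) %% nrow(calls) + 1L])
  }
  markers <- parse_marker_id(colnames(calls))
  if (is.null(family)) {
    ln <- rownames(calls)
    fam <- ifelse(grepl("^Z[0-9]+E", ln), sub("^(Z[0-9]+)E.*$", "\\1", ln), "F1")
    names(fam) <- ln
    family <- fam
  } else {
    family <- family[rownames(calls)]
    if (anyNA(family)) stop("`family` must cover every line")
  }
  structure(list(calls = calls, family = family, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %d families\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$family))))
  cat(sprintf("  heterozygote ratio %.3f, missing ratio %.3f\n",
              mean(x$calls == "Qq"), mean(x$calls == "MISSING")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-marker heterozygote and missing ratios
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `marker`, `het_ratio`, `missing_ratio`.
#' @export
marker_ratios <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  data.frame(marker = colnames(gm$calls),
             het_ratio = colMeans(gm$calls == "Qq"),
             missing_ratio = colMeans(gm$calls == "MISSING"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct / validate a long-format phenotype table
#'
#' @param df data.frame with columns `line`, `env` (positive integer
#'   environment index), `trait`, `value` (numeric).
#' @param gm optional companion [genotype_matrix()]; when supplied every
#'   phenotyped line must be genotyped.
#' @return data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(df, gm = NULL) {
  need <- c("line", "env", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  df$line <- as.character(df$line)
  df$env <- as.integer(df$env)
  df$trait <- as.character(df$trait)
  if (!is.numeric(df$value)) stop("phenotype `value` must be numeric")
  if (any(df$env < 1L)) stop("environment indices must be >= 1")
  key <- paste(df$line, df$env, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate phenotype record for (line=%s, env=%d, trait=%s)",
                 d$line, d$env, d$trait))
  }
  if (!is.null(gm)) {
    unknown <- setdiff(df$line, rownames(gm$calls))
    if (length(unknown)) {
      stop("phenotyped line(s) absent from genotype matrix: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

empty_env_loci <- function() {
  data.frame(marker = character(), env = integer(),
             ae = numeric(), de = numeric(), stringsAsFactors = FALSE)
}

empty_env_pairs <- function() {
  data.frame(marker1 = character(), marker2 = character(), env = integer(),
             aae = numeric(), ade = numeric(), dae = numeric(), dde = numeric(),
             stringsAsFactors = FALSE)
}

canonical_pair_order <- function(m1, m2) {
  p1 <- parse_marker_id(m1); p2 <- parse_marker_id(m2)
  if (any(m1 == m2)) stop("epistatic pair with identical markers")
  # canonical order: lower (chrom, pos) first
  swap <- (p2$chrom < p1$chrom) | (p2$chrom == p1$chrom & p2$pos < p1$pos)
  swap
}

#' Construct a genetic architecture
#'
#' The "truth" (or estimate) of a trait's genetic model: population mean plus
#' per-locus additive/dominance effects, per-pair digenic epistasis effects
#' (`aa`, `ad`, `da`, `dd`), and environment-specific interaction deviations
#' (`ae`, `de`, `aae`, `ade`, `dae`, `dde`).  Pairs are stored in canonical
#' order (lower chromosome/position first); when a pair is supplied in the
#' opposite order its `ad`/`da` (and `ade`/`dae`) effects are swapped so that
#' `ad` always means additive at the first marker times dominance at the
#' second.
#'
#' @param mu population mean.
#' @param loci data.frame(marker, a, d).
#' @param pairs data.frame(marker1, marker2, aa, ad, da, dd).
#' @param env_loci data.frame(marker, env, ae, de).
#' @param env_pairs data.frame(marker1, marker2, env, aae, ade, dae, dde).
#' @param residual_sd nonnegative residual standard deviation.
#' @return object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(mu = 0,
                                 loci = data.frame(marker = character(),
                                                   a = numeric(), d = numeric()),
                                 pairs = data.frame(marker1 = character(), marker2 = character(),
                                                    aa = numeric(), ad = numeric(),
                                                    da = numeric(), dd = numeric()),
                                 env_loci = empty_env_loci(),
                                 env_pairs = empty_env_pairs(),
                                 residual_sd = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, residual_sd >= 0)
  loci <- as.data.frame(loci); pairs <- as.data.frame(pairs)
  env_loci <- as.data.frame(env_loci); env_pairs <- as.data.frame(env_pairs)
  if (nrow(loci) && anyDuplicated(loci$marker)) stop("duplicate locus in architecture")
  if (nrow(pairs)) {
    swap <- canonical_pair_order(pairs$marker1, pairs$marker2)
    if (any(swap)) {
      tmp <- pairs$marker1[swap]
      pairs$marker1[swap] <- pairs$marker2[swap]
      pairs$marker2[swap] <- tmp
      tmp <- pairs$ad[swap]; pairs$ad[swap] <- pairs$da[swap]; pairs$da[swap] <- tmp
    }
    if (anyDuplicated(paste(pairs$marker1, pairs$marker2))) stop("duplicate pair")
  }
  if (nrow(env_pairs)) {
    swap <- canonical_pair_order(env_pairs$marker1, env_pairs$marker2)
    if (any(swap)) {
      tmp <- env_pairs$marker1[swap]
      env_pairs$marker1[swap] <- env_pairs$marker2[swap]
      env_pairs$marker2[swap] <- tmp
      tmp <- env_pairs$ade[swap]; env_pairs$ade[swap] <- env_pairs$dae[swap]
      env_pairs$dae[swap] <- tmp
    }
  }
  structure(list(mu = mu, loci = loci, pairs = pairs,
                 env_loci = env_loci, env_pairs = env_pairs,
                 residual_sd = residual_sd),
            class = "genetic_architecture")
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf("genetic_architecture: mu=%.4g, %d loci, %d pairs, %d env-locus rows, %d env-pair rows, residual_sd=%.4g\n",
              x$mu, nrow(x$loci), nrow(x$pairs), nrow(x$env_loci),
              nrow(x$env_pairs), x$residual_sd))
  invisible(x)
}

#' Additive coefficient coding
#'
#' Codes the non-common-parent homozygote `QQ` as 1 and the common-parent
#' (B73) homozygote `qq` as -1.  Heterozygotes sit at the midpoint, 0, and
#' `MISSING` calls are coded like heterozygotes (the missing-as-heterozygote
#' policy: a missing genotype contributes nothing to the additive contrast).
#'
#' @param call character vector of genotype codes.
#' @return numeric vector in \{-1, 0, 1\}.
#' @export
#' @examples
#' encode_additive(c("QQ", "Qq", "qq", "MISSING"))
encode_additive <- function(call) {
  call[is.na(call)] <- "MISSING"
  bad <- !(call %in% GENO_CODES)
  if (any(bad)) stop("unknown genotype code: '", call[bad][1L], "'")
  unname(c(QQ = 1, Qq = 0, qq = -1, MISSING = 0)[call])
}

#' Dominance coefficient coding
#'
#' Heterozygote indicator (F-infinity metric): `Qq` and `MISSING` are coded 1,
#' homozygotes 0, so the dominance effect `d` is the heterozygote's deviation
#' from the homozygote midpoint.  Coding `MISSING` as a heterozygote is
#' equivalent to attaching an indicator variable to missing calls.
#'
#' @inheritParams encode_additive
#' @return numeric vector in \{0, 1\}.
#' @export
encode_dominance <- function(call) {
  call[is.na(call)] <- "MISSING"
  bad <- !(call %in% GENO_CODES)
  if (any(bad)) stop("unknown genotype code: '", call[bad][1L], "'")
  unname(c(QQ = 0, Qq = 1, qq = 0, MISSING = 1)[call])
}

FIXED_KINDS <- c("a", "d", "aa", "ad", "da", "dd")
RANDOM_KINDS <- c("ae", "de", "aae", "ade", "dae", "dde")
DOMINANCE_KINDS <- c("d", "ad", "da", "dd", "de", "ade", "dae", "dde")

kind_to_env_kind <- function(kind) {
  unname(c(a = "ae", d = "de", aa = "aae", ad = "ade", da = "dae", dd = "dde")[kind])
}

#' Build the mixed-model coefficient design for a trait
#'
#' Expands a genotype matrix and phenotype table into the design consumed by
#' the association tests and the Gibbs sampler: one row per phenotype record;
#' a fixed block holding the intercept, environment indicators and one column
#' per fixed genetic term; and one random block per
#' genotype-by-environment interaction term, each block holding the term's
#' coefficient times the per-environment indicator (E columns).
#'
#' Under the full model each locus contributes `a` and `d` columns and each
#' pair contributes `aa`, `ad`, `da`, `dd` columns (elementwise products of
#' the parent single-locus codings), with matching random interaction blocks
#' `ae`, `de`, `aae`, `ade`, `dae`, `dde`.  Under the additive model only `a`
#' columns and `ae` blocks are emitted.
#'
#' @param gm [genotype_matrix()].
#' @param ph [phenotype_table()].
#' @param trait trait name present in `ph`.
#' @param loci character vector of marker IDs to model.
#' @param pairs optional 2-column matrix/data.frame of marker-ID pairs
#'   (each pair's markers must be in `loci`).
#' @param model `"full"` or `"additive"`.
#' @return object of class `coefficient_design`: list with `y`, `X` (fixed
#'   block), `Z` (named list of random blocks), `registry` (data.frame
#'   column/kind/marker1/marker2/env/block), `env`, `line`, `envs`,
#'   `base_cols`.
#' @export
build_design <- function(gm, ph, trait, loci, pairs = NULL,
                         model = c("full", "additive")) {
  model <- match.arg(model)
  stopifnot(inherits(gm, "genotype_matrix"))
  ph <- phenotype_table(ph, gm)
  if (length(loci) == 0L) stop("empty locus set")
  if (!all(loci %in% colnames(gm$calls))) {
    stop("loci absent from genotype matrix: ",
         paste(setdiff(loci, colnames(gm$calls)), collapse = ", "))
  }
  recs <- ph[ph$trait == trait, , drop = FALSE]
  if (nrow(recs) == 0L) stop("trait '", trait, "' absent from phenotype table")
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
    if (!all(pairs %in% loci)) stop("pair references a locus not in `loci`")
    swap <- canonical_pair_order(pairs[, 1L], pairs[, 2L])
    pairs[swap, ] <- pairs[swap, c(2L, 1L), drop = FALSE][, , drop = FALSE]
  } else {
    pairs <- matrix(character(), 0L, 2L)
  }
  if (model == "additive") pairs <- matrix(character(), 0L, 2L)

  n <- nrow(recs)
  envs <- sort(unique(recs$env))
  E <- length(envs)
  li <- match(recs$line, rownames(gm$calls))

  # single-locus codings, one column per locus, rows aligned to records
  xA <- vapply(loci, function(m) encode_additive(gm$calls[li, m]), numeric(n))
  xD <- vapply(loci, function(m) encode_dominance(gm$calls[li, m]), numeric(n))
  if (n == 1L) { xA <- matrix(xA, 1L); xD <- matrix(xD, 1L)
                 colnames(xA) <- colnames(xD) <- loci }

  base <- cbind(intercept = rep(1, n))
  if (E > 1L) {
    envind <- vapply(envs[-1L], function(h) as.numeric(recs$env == h), numeric(n))
    if (n == 1L) envind <- matrix(envind, 1L)
    colnames(envind) <- paste0("env", envs[-1L])
    base <- cbind(base, envind)
  }

  cols <- list(); reg <- list()
  add_col <- function(name, v, kind, m1, m2 = NA_character_) {
    cols[[name]] <<- v
    reg[[name]] <<- data.frame(column = name, kind = kind, marker1 = m1,
                               marker2 = m2, env = NA_integer_,
                               block = NA_character_, stringsAsFactors = FALSE)
  }
  for (m in loci) {
    add_col(paste0("a:", m), xA[, m], "a", m)
    if (model == "full") add_col(paste0("d:", m), xD[, m], "d", m)
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      m1 <- pairs[k, 1L]; m2 <- pairs[k, 2L]; tag <- paste0(m1, ":", m2)
      add_col(paste0("aa:", tag), xA[, m1] * xA[, m2], "aa", m1, m2)
      add_col(paste0("ad:", tag), xA[, m1] * xD[, m2], "ad", m1, m2)
      add_col(paste0("da:", tag), xD[, m1] * xA[, m2], "da", m1, m2)
      add_col(paste0("dd:", tag), xD[, m1] * xD[, m2], "dd", m1, m2)
    }
  }
  X <- cbind(base, do.call(cbind, c(cols, list(deparse.level = 0))))
  if (length(cols)) colnames(X) <- c(colnames(base), names(cols))

  # random blocks: one per genetic term, E columns each (env-sliced term column)
  Z <- list()
  zreg <- list()
  for (nm in names(cols)) {
    info <- reg[[nm]]
    rkind <- kind_to_env_kind(info$kind)
    blk <- vapply(envs, function(h) cols[[nm]] * (recs$env == h), numeric(n))
    if (n == 1L) blk <- matrix(blk, 1L)
    bname <- sub("^[a-z]+:", paste0(rkind, ":"), nm)
    colnames(blk) <- paste0(bname, "@e", envs)
    Z[[bname]] <- blk
    zreg[[bname]] <- data.frame(column = colnames(blk), kind = rkind,
                                marker1 = info$marker1, marker2 = info$marker2,
                                env = envs, block = bname,
                                stringsAsFactors = FALSE)
  }
  registry <- do.call(rbind, c(reg, zreg))
  rownames(registry) <- NULL
  structure(list(y = recs$value, X = X, Z = Z, registry = registry,
                 env = recs$env, line = recs$line, envs = envs,
                 base_cols = colnames(base), model = model,
                 loci = loci, pairs = pairs, trait = trait),
            class = "coefficient_design")
}

#' @export
print.coefficient_design <- function(x, ...) {
  cat(sprintf("coefficient_design: %d obs, %d fixed columns (%d genetic), %d random blocks, model=%s\n",
              length(x$y), ncol(x$X), ncol(x$X) - length(x$base_cols),
              length(x$Z), x$model))
  invisible(x)
}
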