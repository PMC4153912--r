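#' Configuration for the molecule-tagged read simulator
#'
#' The simulator emulates a molecule-tagging protocol end to end: each
#' template molecule receives a random tag *before* exponential PCR, PCR
#' introduces per-cycle polymerase substitutions (with early-cycle mutations
#' shared by roughly half of a molecule's reads), amplification efficiency
#' varies per molecule (lognormal bias), and sequencing adds
#' position-dependent substitutions whose Phred qualities are calibrated to
#' the error probability actually used.
#'
#' @param templates Character vector of template amplicon sequences, or
#'   `NULL` to generate `n_templates` random sequences of `template_length`.
#' @param n_templates,template_length Used only when `templates` is `NULL`.
#' @param spec A [structure_spec()] describing the tag/primer layout wrapped
#'   around each amplicon.
#' @param n_molecules Number of tagged template molecules (tag keys).
#' @param depth_dist Reads per molecule: `list(dist = "lognormal", meanlog,
#'   sdlog)` (default meanlog 1.0, sdlog 0.7, truncated to >= 1, matching the
#'   right-skewed depth histograms of real tagged libraries) or `list(dist =
#'   "fixed", value = k)`.
#' @param pcr_error_rate Substitutions per base per PCR cycle.
#' @param n_cycles Number of PCR cycles.
#' @param amplification_bias_sd Lognormal sigma of per-molecule amplification
#'   efficiency (0 disables bias).
#' @param seq_error Sequencing-error model: `list(profile = "uniform", rate)`
#'   or `list(profile = "quality_curve", q_start, q_end)` giving a linear
#'   per-position quality ramp from which error rates are derived.
#' @param collision_rate Fraction of tag keys deliberately shared by two
#'   distinct templates (planted "birthday paradox" collisions).
#' @param layout `"merged"`/`"single"` (one whole-fragment read per copy) or
#'   `"paired"` (R1/R2 of `read_length` nt from the fragment ends).
#' @param read_length Mate length for `layout = "paired"`.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(templates = NULL, n_templates = 10L, template_length = 100L,
                       spec = default_sim_spec(),
                       n_molecules = 1000L,
                       depth_dist = list(dist = "lognormal", meanlog = 1.0, sdlog = 0.7),
                       pcr_error_rate = 1e-5, n_cycles = 30L,
                       amplification_bias_sd = 0.3,
                       seq_error = list(profile = "quality_curve", q_start = 38, q_end = 28),
                       collision_rate = 0, layout = c("merged", "single", "paired"),
                       read_length = 150L, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(n_molecules >= 1L, pcr_error_rate >= 0, pcr_error_rate <= 1,
            collision_rate >= 0, collision_rate <= 1, n_cycles >= 0L)
  if (!is.null(templates)) {
    stopifnot(is.character(templates), all(nchar(templates) > 0))
    templates <- toupper(templates)
  }
  structure(list(
    templates = templates, n_templates = as.integer(n_templates),
    template_length = as.integer(template_length), spec = spec,
    n_molecules = as.integer(n_molecules), depth_dist = depth_dist,
    pcr_error_rate = pcr_error_rate, n_cycles = as.integer(n_cycles),
    amplification_bias_sd = amplification_bias_sd, seq_error = seq_error,
    collision_rate = collision_rate, layout = layout,
    read_length = as.integer(read_length), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default read structure used by the simulator
#'
#' 8 nt tags on both ends around the 515F/806R 16S rRNA V4 primer pair, a
#' widely used amplicon design.
#'
#' @param layout Layout passed through to [structure_spec()].
#' @return A [structure_spec()].
#' @export
default_sim_spec <- function(layout = "merged_pair") {
  structure_spec(
    fwd_mt_len = 8L, fwd_primer = "GTGCCAGCMGCCGCGGTAA",
    rev_primer = "GGACTACHVGGGTWTCTAAT", rev_mt_len = 8L,
    layout = layout
  )
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES4, len, replace = TRUE), collapse = "")
  }, character(1))
}

# draw a concrete sequence from an IUPAC pattern (degenerate primer synthesis)
instantiate_iupac <- function(pattern) {
  if (!nchar(pattern)) return("")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    cls <- iupac_to_class(ch)
    if (length(cls) == 1L) cls else sample(cls, 1L)
  }, character(1)), collapse = "")
}

# per-position sequencing error probabilities and calibrated qualities
seq_error_curve <- function(seq_error, len) {
  p <- switch(seq_error$profile,
    uniform = rep(seq_error$rate, len),
    quality_curve = {
      q <- seq(seq_error$q_start, seq_error$q_end, length.out = max(len, 1L))
      10^(-q / 10)
    },
    stop("unknown sequencing-error profile: ", seq_error$profile, call. = FALSE)
  )
  q <- ifelse(p <= 0, 93L, pmin(93L, as.integer(round_half_up(-10 * log10(pmax(p, 1e-10))))))
  list(p = p, qual = phred_encode(q))
}

mutate_positions <- function(chars, pos) {
  if (!length(pos)) return(chars)
  cur <- chars[pos]
  alt <- vapply(cur, function(b) sample(setdiff(BASES4, b), 1L), character(1))
  chars[pos] <- alt
  chars
}

#' Simulate molecule-tagged amplicon reads with ground truth
#'
#' Per molecule: a tag is drawn (uniform over the tag space; a configurable
#' fraction of keys is deliberately reused by a second, different template to
#' plant tag collisions), an early-PCR "founder" mutation may occur (carried
#' by the half of the reads descending from the mutant first-cycle copy),
#' each read additionally accumulates later-cycle PCR substitutions, the
#' molecule's realized depth is its depth draw scaled by a lognormal
#' amplification weight, and sequencing substitutions are applied
#' position-wise with qualities matching the error rates used.
#'
#' @param config A [sim_config()].
#' @return A list: `reads` (read tibble; for `layout = "paired"` instead
#'   `r1`/`r2` tibbles), `truth` (tibble with `read_id`, `tag_key`,
#'   `template_id`, `true_amplicon`, `molecule_id`, plus `true_overlap` and
#'   `fragment_length` for paired output), `molecules` (per-molecule table
#'   with tag, template, amplification weight and realized depth) and the
#'   echoed `config`.
#' @export
simulate_mt_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spec <- config$spec

  templates <- config$templates
  if (is.null(templates)) {
    templates <- random_dna(config$n_templates, config$template_length)
  }
  n_templates <- length(templates)

  tag_len <- spec$fwd_mt_len + spec$rev_mt_len
  n_keys <- config$n_molecules
  if (4^tag_len < n_keys && config$collision_rate == 0) {
    stop("tag space (4^", tag_len, ") smaller than n_molecules; ",
         "collisions are unavoidable", call. = FALSE)
  }
  draw_tags <- function(n, len) {
    if (len == 0L) return(rep("", n))
    tags <- random_dna(n, len)
    while (anyDuplicated(tags)) {
      dup <- which(duplicated(tags))
      tags[dup] <- random_dna(length(dup), len)
    }
    tags
  }
  fwd_tags <- draw_tags(n_keys, spec$fwd_mt_len)
  rev_tags <- draw_tags(n_keys, spec$rev_mt_len)
  keys <- tag_key(ifelse(nchar(fwd_tags) > 0, fwd_tags, NA_character_),
                  ifelse(nchar(rev_tags) > 0, rev_tags, NA_character_))

  template_id <- sample.int(n_templates, n_keys, replace = TRUE)
  mol <- tibble::tibble(
    molecule_id = seq_len(n_keys), key = keys,
    fwd_tag = fwd_tags, rev_tag = rev_tags, template_id = template_id
  )
  n_coll <- round(config$collision_rate * n_keys)
  if (n_coll > 0) {
    if (n_templates < 2L) {
      stop("planting tag collisions requires at least two distinct templates", call. = FALSE)
    }
    extra <- mol[seq_len(n_coll), ]
    extra$molecule_id <- n_keys + seq_len(n_coll)
    extra$template_id <- vapply(extra$template_id, function(t) {
      sample(setdiff(seq_len(n_templates), t), 1L)
    }, integer(1))
    mol <- dplyr::bind_rows(mol, extra)
  }
  n_mol <- nrow(mol)

  # realized depth: depth draw scaled by amplification weight, floored at 1
  d0 <- switch(config$depth_dist$dist,
    lognormal = stats::rlnorm(n_mol, config$depth_dist$meanlog, config$depth_dist$sdlog),
    fixed = rep(config$depth_dist$value, n_mol),
    stop("unknown depth distribution: ", config$depth_dist$dist, call. = FALSE)
  )
  w <- if (config$amplification_bias_sd > 0) {
    stats::rlnorm(n_mol, 0, config$amplification_bias_sd)
  } else {
    rep(1, n_mol)
  }
  mol$amp_weight <- w
  mol$depth <- pmax(1L, as.integer(round_half_up(d0 * w)))

  # structured fragment per molecule (concrete draw of degenerate positions)
  fwd_linker <- spec$fwd_linker
  rev_linker <- spec$rev_linker
  fragments <- vapply(seq_len(n_mol), function(i) {
    paste0(
      mol$fwd_tag[i],
      instantiate_iupac(fwd_linker),
      instantiate_iupac(spec$fwd_primer),
      templates[mol$template_id[i]],
      reverse_complement(instantiate_iupac(spec$rev_primer)),
      reverse_complement(instantiate_iupac(rev_linker)),
      reverse_complement(mol$rev_tag[i])
    )
  }, character(1))

  p_late <- 1 - (1 - config$pcr_error_rate)^max(0L, config$n_cycles - 1L)

  paired <- config$layout == "paired"
  frag_len <- nchar(fragments)
  if (paired && any(config$read_length > frag_len)) {
    stop("read_length exceeds fragment length", call. = FALSE)
  }
  curve_cache <- list()
  get_curve <- function(len) {
    k <- as.character(len)
    if (is.null(curve_cache[[k]])) curve_cache[[k]] <<- seq_error_curve(config$seq_error, len)
    curve_cache[[k]]
  }

  total_reads <- sum(mol$depth)
  seqs1 <- character(total_reads); quals1 <- character(total_reads)
  seqs2 <- character(total_reads); quals2 <- character(total_reads)
  t_key <- character(total_reads); t_tpl <- integer(total_reads)
  t_mol <- integer(total_reads)
  r <- 0L
  for (i in seq_len(n_mol)) {
    frag <- strsplit(fragments[i], "", fixed = TRUE)[[1]]
    L <- length(frag)
    # founder mutation: a cycle-1 substitution shared by one of the two
    # first-cycle lineages, hence by ~half the molecule's reads
    founder <- if (config$pcr_error_rate > 0 &&
                   stats::runif(1) < 1 - (1 - config$pcr_error_rate)^L) {
      frag_mut <- mutate_positions(frag, sample.int(L, 1L))
      frag_mut
    } else NULL
    for (k in seq_len(mol$depth[i])) {
      r <- r + 1L
      chars <- if (!is.null(founder) && stats::runif(1) < 0.5) founder else frag
      if (p_late > 0) {
        pos <- which(stats::runif(L) < p_late)
        chars <- mutate_positions(chars, pos)
      }
      if (paired) {
        RL <- config$read_length
        crv <- get_curve(RL)
        r1 <- chars[seq_len(RL)]
        err1 <- which(stats::runif(RL) < crv$p)
        r1 <- mutate_positions(r1, err1)
        rcc <- rev(chartr("ACGT", "TGCA", chars))
        r2 <- rcc[seq_len(RL)]
        err2 <- which(stats::runif(RL) < crv$p)
        r2 <- mutate_positions(r2, err2)
        seqs1[r] <- paste(r1, collapse = "")
        seqs2[r] <- paste(r2, collapse = "")
        quals1[r] <- crv$qual
        quals2[r] <- crv$qual
      } else {
        crv <- get_curve(L)
        err <- which(stats::runif(L) < crv$p)
        chars <- mutate_positions(chars, err)
        seqs1[r] <- paste(chars, collapse = "")
        quals1[r] <- crv$qual
      }
      t_key[r] <- mol$key[i]
      t_tpl[r] <- mol$template_id[i]
      t_mol[r] <- mol$molecule_id[i]
    }
  }

  ids <- sprintf("sim_%06d", seq_len(total_reads))
  truth <- tibble::tibble(
    read_id = ids, tag_key = t_key, template_id = t_tpl,
    true_amplicon = templates[t_tpl], molecule_id = t_mol
  )
  if (paired) {
    truth$fragment_length <- frag_len[match(t_mol, mol$molecule_id)]
    truth$true_overlap <- 2L * config$read_length - truth$fragment_length
    list(
      r1 = tibble::tibble(id = ids, comment = NA_character_, seq = seqs1,
                          qual = quals1, mate = "fwd"),
      r2 = tibble::tibble(id = ids, comment = NA_character_, seq = seqs2,
                          qual = quals2, mate = "rev"),
      truth = truth, molecules = mol, config = config
    )
  } else {
    list(
      reads = tibble::tibble(id = ids, comment = NA_character_, seq = seqs1,
                             qual = quals1, mate = "single"),
      truth = truth, molecules = mol, config = config
    )
  }
}

#' Errors per base against the simulator's ground truth
#'
#' Records are matched to their true amplicon by `read_id` when present in
#' the truth table, otherwise by tag key. A position counts as an error iff
#' the true base is *not* in the IUPAC expansion of the called base (so an
#' ambiguity call covering the truth is not an error). When a tag key maps to
#' several templates (a planted collision), the template with most reads for
#' that key is used. Records whose key is absent from the truth table are
#' excluded and counted.
#'
#' @param records Tibble with a `seq` column plus `id` (raw reads) or `key`
#'   (consensus sequences); an optional `depth` column defines the grouping.
#' @param truth Truth tibble from [simulate_mt_reads()].
#' @return A tibble grouped by depth: `depth`, `n`, `mean_epb`, `se`; the
#'   per-record table is attached as attribute `"per_record"` and the number
#'   of unresolvable records as attribute `"n_unknown"`.
#' @export
evaluate_epb <- function(records, truth) {
  stopifnot("seq" %in% names(records))
  if ("id" %in% names(records) && any(records$id %in% truth$read_id)) {
    ref <- truth$true_amplicon[match(records$id, truth$read_id)]
  } else if ("key" %in% names(records)) {
    key_map <- truth |>
      dplyr::count(.data$tag_key, .data$template_id, .data$true_amplicon) |>
      dplyr::group_by(.data$tag_key) |>
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    ref <- key_map$true_amplicon[match(records$key, key_map$tag_key)]
  } else {
    stop("records need an 'id' or 'key' column resolvable against the truth table",
         call. = FALSE)
  }
  known <- !is.na(ref)
  n_unknown <- sum(!known)
  rec <- records[known, , drop = FALSE]
  ref <- ref[known]
  epb <- vapply(seq_len(nrow(rec)), function(i) {
    called <- strsplit(rec$seq[i], "", fixed = TRUE)[[1]]
    true <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    L <- min(length(called), length(true))
    errs <- abs(length(called) - length(true))
    if (L > 0) {
      cov <- IUPAC_COVERS[cbind(called[seq_len(L)], true[seq_len(L)])]
      errs <- errs + sum(!cov)
    }
    errs / max(length(true), 1L)
  }, numeric(1))
  depth <- if ("depth" %in% names(rec)) rec$depth else rep(1L, nrow(rec))
  per_record <- tibble::tibble(depth = depth, epb = epb)
  out <- per_record |>
    dplyr::group_by(.data$depth) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_epb = mean(.data$epb),
      se = stats::sd(.data$epb) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  attr(out, "per_record") <- per_record
  attr(out, "n_unknown") <- n_unknown
  out
}
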