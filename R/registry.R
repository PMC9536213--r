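#' Load the synapse-class registry
#'
#' Reads the packaged table of 29 connection classes (or a user-supplied file in
#' the same TSV layout). `legacy_id` is the class label used in the source
#' experimental characterization, kept for cross-reference. Each class carries its short-term-dynamics type
#' (s-type: facilitating E1/I1, depressing E2/I2, pseudo-linear E3/I3), its
#' projection type (p-type: EE/EI/IE/II), kinetic and plasticity parameters as
#' mean +/- standard deviation, and a textual pre:post cell-type rule. Rules are
#' parsed on load and kept as a list column.
#'
#' @param path Path to the registry TSV; defaults to the packaged table.
#' @return A tibble of 29 classes with a `rule_parsed` list column.
#' @export
#' @examples
#' reg <- load_synapse_table()
#' nrow(reg)
load_synapse_table <- function(path = tcsim_extdata("synapse_classes.tsv")) {
  reg <- read_tsv_strict(path)
  needed <- c("index", "legacy_id", "s_type", "p_type", "g_syn_mean", "g_syn_sd",
              "tau_decay_mean", "tau_decay_sd", "U_mean", "U_sd",
              "D_mean", "D_sd", "F_mean", "F_sd", "rule")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0)
    abort(paste0("registry file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  num_cols <- setdiff(needed, c("s_type", "p_type", "rule"))
  for (cc in num_cols) {
    if (!is.numeric(reg[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(reg[[cc]]))))
      abort(sprintf("non-numeric value in column %s, row %d", cc, bad[1]))
    }
  }
  means <- c("g_syn_mean", "tau_decay_mean", "D_mean", "F_mean")
  if (any(as.matrix(reg[, means]) <= 0))
    abort("all kinetic/plasticity means must be positive")
  if (any(reg$U_mean <= 0 | reg$U_mean >= 1)) abort("U means must lie in (0,1)")
  reg$rule_parsed <- lapply(reg$rule, parse_rule)
  class(reg) <- c("tc_registry", class(reg))
  reg
}

# ---------------------------------------------------------------------------
# Rule-pattern grammar
#
# rule        := alternative (" or " alternative)*
# alternative := side ":" side | side          (a bare side inherits the post
#                                               side of a sibling alternative)
# side        := "[" unit ("-" unit)* "]"      top-level "-" outside parens
#              | "(" unit (" " unit)* ")"      space-separated exemplars
#              | unit
# unit        := [layer "_"] (keyword | mtypes ["_" etypes])
# mtypes      := name ("-" name)* | "(" name ("-" name)* ")"
# etypes      := etype | "(" etype (" " etype)* ")"
# keyword     := "Exc" | "Excitatory" | "Inhibitory"
#
# An m-type token matches a cell m-type exactly (case-insensitively) or as a
# prefix whose continuation starts with a digit (so "TTPC" matches "TTPC2" and
# "TPC_L" matches "TPC_L4", but "BP" does not match "BPC").
# ---------------------------------------------------------------------------

.tc_layers <- c("L1", "L23", "L4", "L5", "L6")
.tc_etype_rx <- "^[a-d][A-Z]"

# split `s` on `split` only at parenthesis depth 0
split_top <- function(s, split) {
  depth <- 0L
  out <- character()
  cur <- ""
  chars <- strsplit(s, "")[[1]]
  i <- 1L
  n <- length(chars)
  k <- nchar(split)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L && i + k - 1L <= n &&
        substr(s, i, i + k - 1L) == split) {
      out <- c(out, cur)
      cur <- ""
      i <- i + k
    } else {
      cur <- paste0(cur, ch)
      i <- i + 1L
    }
  }
  c(out, cur)
}

parse_unit <- function(u) {
  u <- trimws(u)
  unit <- list(layer = NA_character_, mtypes = NULL, etypes = NULL,
               ei = NA_character_)
  if (u %in% c("Exc", "Excitatory")) { unit$ei <- "E"; return(unit) }
  if (u %in% c("Inh", "Inhibitory")) { unit$ei <- "I"; return(unit) }
  m <- regmatches(u, regexpr("^(L1|L23|L4|L5|L6)(_|$)", u))
  if (length(m) == 1 && nzchar(m)) {
    unit$layer <- sub("_$", "", m)
    u <- sub("^(L1|L23|L4|L5|L6)_?", "", u)
    if (!nzchar(u)) return(unit)
    if (u %in% c("Exc", "Excitatory")) { unit$ei <- "E"; return(unit) }
    if (u %in% c("Inh", "Inhibitory")) { unit$ei <- "I"; return(unit) }
  }
  # split m-type part from e-type part
  if (grepl("_\\(", u)) {
    pos <- regexpr("_\\(", u)
    mpart <- substr(u, 1, pos - 1)
    epart <- substr(u, pos + 1, nchar(u))
  } else {
    toks <- split_top(u, "_")
    is_e <- grepl(.tc_etype_rx, toks)
    # trailing e-type-looking tokens form the e-type part
    cut <- length(toks) + 1L
    while (cut > 2L && is_e[cut - 1L]) cut <- cut - 1L
    mpart <- paste(toks[seq_len(cut - 1L)], collapse = "_")
    epart <- if (cut <= length(toks))
      paste(toks[cut:length(toks)], collapse = " ") else ""
  }
  mpart <- gsub("^\\(|\\)$", "", mpart)
  unit$mtypes <- strsplit(mpart, "-", fixed = TRUE)[[1]]
  if (nzchar(epart)) {
    epart <- gsub("^\\(|\\)$", "", epart)
    unit$etypes <- strsplit(trimws(epart), "[ -]+")[[1]]
  }
  unit
}

parse_side <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "[") && endsWith(s, "]")) {
    inner <- substr(s, 2, nchar(s) - 1)
    return(lapply(split_top(inner, "-"), parse_unit))
  }
  if (startsWith(s, "(") && endsWith(s, ")")) {
    # does the paren opened at position 1 close at the end?
    depth <- 0L
    chars <- strsplit(s, "")[[1]]
    close_at <- NA_integer_
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") { depth <- depth - 1L
        if (depth == 0L) { close_at <- i; break } }
    }
    if (identical(close_at, length(chars)) && grepl(" ", s)) {
      inner <- substr(s, 2, nchar(s) - 1)
      return(lapply(strsplit(trimws(inner), "\\s+")[[1]], parse_unit))
    }
  }
  list(parse_unit(s))
}

parse_rule <- function(rule) {
  alts_raw <- strsplit(rule, " or ", fixed = TRUE)[[1]]
  parts <- lapply(alts_raw, function(a) split_top(a, ":"))
  n_sides <- vapply(parts, length, integer(1))
  if (any(n_sides > 2)) abort(paste0("malformed rule: ", rule))
  # bare pre-only alternatives inherit the post side of a sibling
  post_raw <- vapply(parts, function(p) if (length(p) == 2) p[[2]] else NA_character_,
                     character(1))
  if (all(is.na(post_raw))) abort(paste0("rule has no post side: ", rule))
  for (i in seq_along(parts)) {
    if (is.na(post_raw[i])) {
      donor <- c(which(!is.na(post_raw) & seq_along(post_raw) > i),
                 which(!is.na(post_raw)))[1]
      parts[[i]] <- c(parts[[i]], post_raw[donor])
    }
  }
  lapply(parts, function(p) list(pre = parse_side(p[[1]]),
                                 post = parse_side(p[[2]])))
}

#' Split an me-type name into its components
#'
#' Names follow the `layer_mtype_etype` convention (for example,
#' `L5_TTPC2_cADpyr`); m-types may themselves contain underscores
#' (`L6_TPC_L4_cADpyr`). By the naming convention of the catalogue, excitatory
#' cells carry the `cADpyr` e-type.
#'
#' @param me_type Character vector of me-type names.
#' @return A tibble with columns `me_type`, `layer`, `m_type`, `e_type`,
#'   `excitatory`.
#' @export
parse_me_type <- function(me_type) {
  parts <- strsplit(me_type, "_", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3 || !(p[1] %in% .tc_layers),
                logical(1))
  if (any(bad))
    abort(paste0("not a layer_mtype_etype name: ", me_type[bad][1]))
  tibble(me_type = me_type,
         layer = vapply(parts, `[[`, character(1), 1),
         m_type = vapply(parts, function(p)
           paste(p[2:(length(p) - 1)], collapse = "_"), character(1)),
         e_type = vapply(parts, function(p) p[[length(p)]], character(1)),
         excitatory = vapply(parts, function(p) p[[length(p)]] == "cADpyr",
                             logical(1)))
}

match_mtype_token <- function(token, m_type) {
  tt <- toupper(token); mm <- toupper(m_type)
  if (tt == mm) return(TRUE)
  if (startsWith(mm, tt)) {
    nxt <- substr(mm, nchar(tt) + 1, nchar(tt) + 1)
    return(grepl("^[0-9]$", nxt))
  }
  FALSE
}

# returns -1 on no match, else the unit's specificity
match_unit_spec <- function(unit, info) {
  spec <- 0L
  if (!is.na(unit$layer)) {
    if (unit$layer != info$layer) return(-1L)
    spec <- spec + 1L
  }
  if (!is.na(unit$ei)) {
    if ((unit$ei == "E") != info$excitatory) return(-1L)
  }
  if (!is.null(unit$mtypes)) {
    if (!any(vapply(unit$mtypes, match_mtype_token, logical(1), info$m_type)))
      return(-1L)
    spec <- spec + 1L
  }
  if (!is.null(unit$etypes)) {
    if (!(info$e_type %in% unit$etypes)) return(-1L)
    spec <- spec + 1L
  }
  spec
}

match_side_spec <- function(side, info) {
  specs <- vapply(side, match_unit_spec, integer(1), info)
  if (all(specs < 0)) -1L else max(specs)
}

#' Match a connection class from pre/post me-type names
#'
#' Evaluates all 29 rule patterns against the ordered pair and returns the
#' matching class. When several rules match, the most specific wins
#' (specificity counts constrained tokens: layer, m-type and e-type, summed
#' over both sides); remaining ties resolve to the highest table index.
#'
#' @param registry Registry from [load_synapse_table()].
#' @param pre_me_type,post_me_type me-type names of the pre- and post-synaptic
#'   cells.
#' @return The matched registry row (one-row tibble).
#' @export
#' @examples
#' reg <- load_synapse_table()
#' match_class(reg, "L23_PC_cADpyr", "L23_PC_cADpyr")$index
match_class <- function(registry, pre_me_type, post_me_type) {
  pre <- as.list(parse_me_type(pre_me_type)[1, ])
  post <- as.list(parse_me_type(post_me_type)[1, ])
  best_i <- NA_integer_
  best_spec <- -1L
  for (i in seq_len(nrow(registry))) {
    for (alt in registry$rule_parsed[[i]]) {
      sp_pre <- match_side_spec(alt$pre, pre)
      if (sp_pre < 0) next
      sp_post <- match_side_spec(alt$post, post)
      if (sp_post < 0) next
      spec <- sp_pre + sp_post
      if (spec > best_spec || (spec == best_spec && !is.na(best_i) && i > best_i)) {
        best_spec <- spec
        best_i <- i
      }
    }
  }
  if (is.na(best_i))
    abort(sprintf("no synapse class matches pair %s -> %s",
                  pre_me_type, post_me_type))
  registry[best_i, ]
}

#' Receptor implied by an s-type
#'
#' Excitatory classes are AMPA-mediated, inhibitory classes GABA_A-mediated.
#'
#' @param s_type Character vector of s-types (`E1`..`E3`, `I1`..`I3`).
#' @return Character vector: `"AMPA"` or `"GABA_A"`.
#' @export
receptor_for_s_type <- function(s_type) {
  ifelse(startsWith(s_type, "E"), "AMPA", "GABA_A")
}

#' Sample per-synapse parameters from a class
#'
#' Draws each parameter from a normal distribution with the class's mean and
#' standard deviation, truncated below at 1% of the mean so kinetics stay
#' positive; U is additionally truncated to (0, 1]. The rise time is fixed at
#' 0.2 ms for all synapses.
#'
#' @param registry Registry from [load_synapse_table()].
#' @param class_index Class index (0-28).
#' @param n Number of synapses to draw.
#' @return A tibble with columns `g_syn`, `tau_rise`, `tau_decay`, `U`, `D`,
#'   `F`, `s_type`, `receptor`.
#' @export
sample_synapse_params <- function(registry, class_index, n = 1) {
  row <- registry[registry$index == class_index, ]
  if (nrow(row) != 1) abort(paste0("unknown class index: ", class_index))
  U <- pmin(pmax(rnorm(n, row$U_mean, row$U_sd), 0.01 * row$U_mean), 1)
  tibble(class_index = class_index,
         g_syn = rnorm_trunc(n, row$g_syn_mean, row$g_syn_sd),
         tau_rise = 0.2,
         tau_decay = rnorm_trunc(n, row$tau_decay_mean, row$tau_decay_sd),
         U = U,
         D = rnorm_trunc(n, row$D_mean, row$D_sd),
         F = rnorm_trunc(n, row$F_mean, row$F_sd),
         s_type = row$s_type,
         receptor = receptor_for_s_type(row$s_type))
}

#' Calcium-dependent synaptic state
#'
#' Extracellular calcium controls release probability. The in-vitro state uses
#' `cao = 2.0` mM with unit multipliers; the in-vivo-like state uses
#' `cao = 1.2` mM and scales U by a dependence-class multiplier. The class
#' multipliers default to the endpoints and midpoint of the 0.25-0.75 range
#' (steep 0.25, intermediate 0.50, shallow 0.75) and can be overridden.
#'
#' @param cao Extracellular calcium concentration in mM.
#' @param multipliers Named numeric vector with entries `steep`,
#'   `intermediate`, `shallow`, all in (0, 1].
#' @return A `tc_calcium` object.
#' @export
calcium_state <- function(cao = 2.0, multipliers = NULL) {
  if (is.null(multipliers)) {
    multipliers <- if (cao >= 2.0) {
      c(steep = 1, intermediate = 1, shallow = 1)
    } else {
      c(steep = 0.25, intermediate = 0.50, shallow = 0.75)
    }
  }
  if (any(multipliers <= 0 | multipliers > 1))
    abort("calcium multipliers must lie in (0, 1]")
  structure(list(cao = cao, multipliers = multipliers), class = "tc_calcium")
}

.tc_distal_targets <- c("DBC", "BTC", "MC", "BP")
.tc_proximal_targets <- c("LBC", "NBC", "SBC", "CHC")

#' Calcium-dependence class of a connection
#'
#' Pyramidal-cell connections onto other pyramidal cells and onto
#' distal-targeting interneurons (DBC, BTC, MC, BP) have steep dependence;
#' pyramidal connections onto proximal-targeting interneurons (LBC, NBC, SBC,
#' ChC) have shallow dependence; all other connections are intermediate.
#'
#' @param pre_excitatory Logical vector: presynaptic cell excitatory?
#' @param post_m_type Character vector of postsynaptic m-types.
#' @param post_excitatory Logical vector: postsynaptic cell excitatory?
#' @return Character vector in `c("steep", "intermediate", "shallow")`.
#' @export
dependence_class <- function(pre_excitatory, post_m_type, post_excitatory) {
  post_up <- toupper(post_m_type)
  out <- rep("intermediate", length(post_m_type))
  out[pre_excitatory & post_excitatory] <- "steep"
  out[pre_excitatory & post_up %in% .tc_distal_targets] <- "steep"
  out[pre_excitatory & post_up %in% .tc_proximal_targets] <- "shallow"
  out
}

#' Apply calcium-dependent rescaling to synapse parameters
#'
#' Multiplies U by the dependence-class multiplier of the connection; all other
#' parameters (and the s-type label) are unchanged.
#'
#' @param params Parameter tibble from [sample_synapse_params()] (must contain
#'   a `U` column).
#' @param pre_me_type,post_me_type me-type names of the connection.
#' @param state A [calcium_state()].
#' @return `params` with rescaled `U`.
#' @export
apply_calcium_scaling <- function(params, pre_me_type, post_me_type, state) {
  pre <- parse_me_type(pre_me_type)
  post <- parse_me_type(post_me_type)
  dep <- dependence_class(pre$excitatory, post$m_type, post$excitatory)
  params$U <- params$U * unname(state$multipliers[dep])
  params
}
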