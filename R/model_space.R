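#' Region sets
#'
#' A region set is an ordered collection of unique region labels. The
#' canonical four-region auditory network is left/right Heschl's gyrus (LHG,
#' RHG) and left/right superior temporal gyrus (LSTG, RSTG), in the fixed
#' order LHG, LSTG, RHG, RSTG.
#'
#' @param labels character vector of unique, non-empty region names.
#' @return An object of class `dcm_regions` with fields `labels` and `n`.
#' @export
#' @examples
#' region_set(c("A", "B"))
#' auditory_regions()
region_set <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a region set needs at least 2 regions")
  if (anyDuplicated(labels) || any(!nzchar(labels)) || anyNA(labels)) {
    stop("region labels must be unique and non-empty")
  }
  structure(list(labels = labels, n = length(labels)), class = "dcm_regions")
}

#' @rdname region_set
#' @export
auditory_regions <- function() {
  region_set(c("LHG", "LSTG", "RHG", "RSTG"))
}

#' @export
print.dcm_regions <- function(x, ...) {
  cat("<dcm_regions> ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

zero_mat <- function(n, m = n, regions = NULL) {
  z <- matrix(0L, n, m)
  if (!is.null(regions)) dimnames(z) <- list(regions, if (m == n) regions else NULL)
  z
}

#' Construct a model specification
#'
#' A model specification records which couplings exist: `a_support` marks
#' directed connections (entry `(i, j)` is the influence of region `j`, the
#' column/source, on region `i`, the row/target), `c_support` marks where
#' each external input drives the network, `b_supports` marks which
#' connections each input modulates, and `d_supports` marks which
#' connections each region's activity gates (the non-linear extension).
#' Diagonal entries of `a_support` are self-connections and are always
#' treated as present; they are parameterized separately for stability.
#' A spec whose `d_supports` are all zero is bilinear, otherwise non-linear.
#'
#' @param regions a `dcm_regions` object.
#' @param a_support n x n binary matrix of allowed connections.
#' @param c_support n x m binary matrix of driving-input entries.
#' @param b_supports list of m n x n binary matrices (input modulation);
#'   defaults to all-zero.
#' @param d_supports list of n n x n binary matrices (regional gating);
#'   defaults to all-zero.
#' @param name identifier for the model.
#' @return An object of class `dcm_model_spec`.
#' @seealso [validate_spec()], [build_fully_connected()]
#' @export
model_spec <- function(regions, a_support, c_support,
                       b_supports = NULL, d_supports = NULL,
                       name = "model") {
  stopifnot(inherits(regions, "dcm_regions"))
  n <- regions$n
  a_support <- as_binary_matrix(a_support, n, n, "a_support")
  diag(a_support) <- 1L  # self-connections always present
  c_support <- as_binary_matrix(c_support, n, NULL, "c_support")
  m <- ncol(c_support)
  if (is.null(b_supports)) b_supports <- rep(list(zero_mat(n)), m)
  if (is.null(d_supports)) d_supports <- rep(list(zero_mat(n)), n)
  b_supports <- lapply(seq_along(b_supports), function(k) {
    as_binary_matrix(b_supports[[k]], n, n, sprintf("b_supports[%d]", k))
  })
  d_supports <- lapply(seq_along(d_supports), function(k) {
    as_binary_matrix(d_supports[[k]], n, n, sprintf("d_supports[%d]", k))
  })
  lab <- regions$labels
  dimnames(a_support) <- list(lab, lab)
  rownames(c_support) <- lab
  spec <- structure(
    list(regions = regions, a_support = a_support, c_support = c_support,
         b_supports = b_supports, d_supports = d_supports,
         name = as.character(name)),
    class = "dcm_model_spec")
  viol <- validate_spec(spec)
  if (length(viol)) stop("invalid model spec: ", paste(viol, collapse = "; "))
  spec
}

as_binary_matrix <- function(x, nrow, ncol, what) {
  x <- as.matrix(x)
  if (nrow(x) != nrow || (!is.null(ncol) && ncol(x) != ncol)) {
    stop(what, " has wrong dimensions")
  }
  if (!all(x %in% c(0, 1))) stop(what, " must be binary (0/1)")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.dcm_model_spec <- function(x, ...) {
  n_con <- sum(x$a_support) - x$regions$n
  cat(sprintf("<dcm_model_spec> %s: %d regions, %d connections, %d input(s)%s%s\n",
              x$name, x$regions$n, n_con, ncol(x$c_support),
              if (sum(vapply(x$b_supports, sum, 0)) > 0) ", modulated" else "",
              if (is_nonlinear_spec(x)) ", non-linear" else ""))
  invisible(x)
}

#' @rdname model_spec
#' @param spec a `dcm_model_spec`.
#' @export
is_nonlinear_spec <- function(spec) {
  any(vapply(spec$d_supports, sum, numeric(1)) > 0)
}

#' Validate a model specification
#'
#' Checks all structural invariants of a `dcm_model_spec` and reports every
#' violation found; it never throws. An empty return value means the spec is
#' valid.
#'
#' @param spec object to validate (fields as in [model_spec()]).
#' @return Character vector of violation messages (empty if valid), each
#'   naming the offending matrix and index.
#' @export
validate_spec <- function(spec) {
  v <- character(0)
  n <- spec$regions$n
  add <- function(msg) v <<- c(v, msg)
  chk_dim <- function(mat, what) {
    if (!is.matrix(mat) || nrow(mat) != n || ncol(mat) != n) {
      add(sprintf("%s: expected %dx%d matrix", what, n, n)); FALSE
    } else TRUE
  }
  if (!chk_dim(spec$a_support, "a_support")) return(v)
  if (!is.matrix(spec$c_support) || nrow(spec$c_support) != n) {
    add(sprintf("c_support: expected %d rows", n))
    return(v)
  }
  m <- ncol(spec$c_support)
  if (length(spec$b_supports) != m) {
    add(sprintf("b_supports: expected %d matrices (one per input), got %d",
                m, length(spec$b_supports)))
  }
  if (length(spec$d_supports) != n) {
    add(sprintf("d_supports: expected %d matrices (one per region), got %d",
                n, length(spec$d_supports)))
  }
  if (any(diag(spec$a_support) != 1)) add("a_support: diagonal must be all 1 (self-connections)")
  sub_of_a <- function(mat, what) {
    bad <- which(mat != 0 & spec$a_support == 0, arr.ind = TRUE)
    for (r in seq_len(nrow(bad))) {
      add(sprintf("%s[%d,%d]: support outside a_support", what, bad[r, 1], bad[r, 2]))
    }
  }
  for (k in seq_along(spec$b_supports)) {
    if (chk_dim(spec$b_supports[[k]], sprintf("b_supports[%d]", k))) {
      sub_of_a(spec$b_supports[[k]], sprintf("b_supports[%d]", k))
    }
  }
  for (k in seq_along(spec$d_supports)) {
    if (chk_dim(spec$d_supports[[k]], sprintf("d_supports[%d]", k))) {
      sub_of_a(spec$d_supports[[k]], sprintf("d_supports[%d]", k))
    }
  }
  v
}

#' Fully connected input-candidate models
#'
#' Builds a fully connected, non-modulated model with a single external
#' input driving the named regions. These are the stage-1 candidates used to
#' decide where a stimulus enters a network: "Model A" drives bilateral HG,
#' "Model B" drives bilateral STG.
#'
#' @param regions a `dcm_regions` object.
#' @param input_regions character vector (subset of `regions$labels`) that
#'   receive the driving input.
#' @param name model identifier.
#' @return A `dcm_model_spec` with every off-diagonal connection present,
#'   one input column, and no modulation or gating.
#' @export
#' @examples
#' build_fully_connected(auditory_regions(), c("LSTG", "RSTG"))
build_fully_connected <- function(regions, input_regions,
                                  name = paste0("full_input_",
                                                paste(input_regions, collapse = "+"))) {
  stopifnot(inherits(regions, "dcm_regions"))
  input_regions <- unique(as.character(input_regions))
  if (length(input_regions) == 0L) stop("input_regions must be non-empty")
  unknown <- setdiff(input_regions, regions$labels)
  if (length(unknown)) stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  n <- regions$n
  a <- matrix(1L, n, n)
  cmat <- matrix(0L, n, 1)
  cmat[match(input_regions, regions$labels), 1] <- 1L
  model_spec(regions, a, cmat, name = name)
}

#' The pruned winning skeleton
#'
#' The group analysis of the four-region auditory network retains exactly
#' four directed connections - from each STG to both the ipsilateral and the
#' contralateral HG - with the driving input at bilateral STG. This builds
#' that model.
#'
#' @param regions the canonical four-region set ([auditory_regions()]).
#' @return A `dcm_model_spec` named `"pruned_winner"` with connections
#'   LSTG->LHG, LSTG->RHG, RSTG->LHG, RSTG->RHG and input at both STG.
#' @export
build_pruned_winner <- function(regions = auditory_regions()) {
  canon <- auditory_regions()
  if (!inherits(regions, "dcm_regions") || !identical(regions$labels, canon$labels)) {
    stop("build_pruned_winner requires the canonical LHG/LSTG/RHG/RSTG region set")
  }
  n <- regions$n
  a <- zero_mat(n, regions = regions$labels)
  for (con in list(c("LSTG", "LHG"), c("LSTG", "RHG"),
                   c("RSTG", "LHG"), c("RSTG", "RHG"))) {
    a[con[2], con[1]] <- 1L  # (target, source)
  }
  diag(a) <- 1L
  cmat <- matrix(0L, n, 1)
  cmat[match(c("LSTG", "RSTG"), regions$labels), 1] <- 1L
  model_spec(regions, a, cmat, name = "pruned_winner")
}

connection_pairs <- function(spec) {
  idx <- which(spec$a_support == 1 & row(spec$a_support) != col(spec$a_support),
               arr.ind = TRUE)
  lab <- spec$regions$labels
  data.frame(source = lab[idx[, 2]], target = lab[idx[, 1]],
             stringsAsFactors = FALSE)
}

resolve_connections <- function(spec, cons, what) {
  # cons: list of c(source, target); returns arr.ind matrix into a_support
  avail <- connection_pairs(spec)
  out <- matrix(0L, length(cons), 2)
  for (k in seq_along(cons)) {
    con <- cons[[k]]
    hit <- which(avail$source == con[1] & avail$target == con[2])
    if (length(hit) != 1L) {
      stop(what, ": connection ", con[1], "->", con[2], " not present in base model")
    }
    out[k, ] <- c(match(con[2], spec$regions$labels),
                  match(con[1], spec$regions$labels))
  }
  out
}

has_canonical_four <- function(spec) {
  canon <- list(c("LSTG", "LHG"), c("LSTG", "RHG"),
                c("RSTG", "LHG"), c("RSTG", "RHG"))
  if (!identical(spec$regions$labels, auditory_regions()$labels)) return(FALSE)
  all(vapply(canon, function(con) {
    spec$a_support[con[2], con[1]] == 1
  }, logical(1)))
}

default_modulation_sets <- function(spec) {
  # On the canonical pruned winner: six subsets of its four connections,
  # spanning the plausible single-input modulation patterns - all four, the
  # ipsilateral pair, the contralateral pair, each STG's own pair, none.
  if (has_canonical_four(spec)) {
    return(list(
      all_four      = list(c("LSTG", "LHG"), c("LSTG", "RHG"),
                           c("RSTG", "LHG"), c("RSTG", "RHG")),
      ipsilateral   = list(c("LSTG", "LHG"), c("RSTG", "RHG")),
      contralateral = list(c("LSTG", "RHG"), c("RSTG", "LHG")),
      left_pair     = list(c("LSTG", "LHG"), c("LSTG", "RHG")),
      right_pair    = list(c("RSTG", "LHG"), c("RSTG", "RHG")),
      none          = list()
    ))
  }
  # Generic fallback for an arbitrary skeleton: all connections modulated,
  # each source region's outgoing connections modulated, none.
  cons <- connection_pairs(spec)
  out <- list(all = lapply(seq_len(nrow(cons)),
                           function(i) c(cons$source[i], cons$target[i])))
  for (src in unique(cons$source)) {
    sel <- which(cons$source == src)
    out[[paste0("from_", src)]] <- lapply(sel, function(i) {
      c(cons$source[i], cons$target[i])
    })
  }
  out$none <- list()
  out
}

#' Bilinear model family
#'
#' Derives a family of bilinear models from a base skeleton by letting the
#' external input modulate chosen subsets of the base connections. The
#' default family contains six members; its first member ("Model 1", all
#' four connections modulated) is the winning bilinear structure of the
#' four-region auditory analysis.
#'
#' @param base a `dcm_model_spec`, normally [build_pruned_winner()].
#' @param variants named list of modulation descriptors; each descriptor is
#'   a list of `c(source, target)` connection pairs to be input-modulated
#'   (an empty descriptor yields an unmodulated copy of the base).
#' @return List of `dcm_model_spec`, one per descriptor, all sharing the
#'   base `a_support` and all with zero `d_supports` (bilinear).
#' @export
build_bilinear_family <- function(base, variants = default_modulation_sets(base)) {
  stopifnot(inherits(base, "dcm_model_spec"))
  if (is.null(names(variants))) names(variants) <- paste0("variant", seq_along(variants))
  lapply(seq_along(variants), function(k) {
    idx <- resolve_connections(base, variants[[k]], "build_bilinear_family")
    b <- zero_mat(base$regions$n)
    b[idx] <- 1L
    model_spec(base$regions, base$a_support, base$c_support,
               b_supports = list(b),
               name = paste0("bilinear_", names(variants)[k]))
  })
}

default_gating_sets <- function(spec) {
  # On the canonical pruned winner: six gating patterns (gating region ->
  # gated connection). The "stg_own" member is the winning non-linear
  # structure: each STG gates the connections from the ipsilateral STG to
  # both HG.
  if (has_canonical_four(spec)) {
    return(list(
      stg_own = list(list("LSTG", c("LSTG", "LHG")), list("LSTG", c("LSTG", "RHG")),
                     list("RSTG", c("RSTG", "LHG")), list("RSTG", c("RSTG", "RHG"))),
      stg_left = list(list("LSTG", c("LSTG", "LHG")), list("LSTG", c("LSTG", "RHG"))),
      stg_right = list(list("RSTG", c("RSTG", "LHG")), list("RSTG", c("RSTG", "RHG"))),
      hg_incoming = list(list("LHG", c("LSTG", "LHG")), list("LHG", c("RSTG", "LHG")),
                         list("RHG", c("LSTG", "RHG")), list("RHG", c("RSTG", "RHG"))),
      stg_cross = list(list("LSTG", c("RSTG", "LHG")), list("LSTG", c("RSTG", "RHG")),
                       list("RSTG", c("LSTG", "LHG")), list("RSTG", c("LSTG", "RHG"))),
      none = list()
    ))
  }
  # Generic fallback: each source region gates its own outgoing
  # connections, all sources gate their own connections, none.
  cons <- connection_pairs(spec)
  own <- function(src) {
    sel <- which(cons$source == src)
    lapply(sel, function(i) list(src, c(cons$source[i], cons$target[i])))
  }
  out <- list(all_own = do.call(c, c(lapply(unique(cons$source), own),
                                     list(list()))))
  for (src in unique(cons$source)) out[[paste0("own_", src)]] <- own(src)
  out$none <- list()
  out
}

#' Non-linear model family
#'
#' Derives a family of non-linear models from a base skeleton by letting the
#' activity of chosen regions gate chosen base connections (the D-matrix
#' extension of the neuronal model). The default family contains six
#' members; its first member ("Model 10", each STG gating its own outgoing
#' connections to both HG) is the winning non-linear structure.
#'
#' @param base a `dcm_model_spec`, normally [build_pruned_winner()].
#' @param variants named list of gating descriptors; each descriptor is a
#'   list of `list(gating_region, c(source, target))` pairs. An empty
#'   descriptor yields a bilinear-equivalent copy of the base.
#' @return List of `dcm_model_spec`, one per descriptor.
#' @export
build_nonlinear_family <- function(base, variants = default_gating_sets(base)) {
  stopifnot(inherits(base, "dcm_model_spec"))
  if (is.null(names(variants))) names(variants) <- paste0("variant", seq_along(variants))
  lab <- base$regions$labels
  lapply(seq_along(variants), function(k) {
    d <- rep(list(zero_mat(base$regions$n)), base$regions$n)
    for (g in variants[[k]]) {
      j <- match(g[[1]], lab)
      if (is.na(j)) stop("build_nonlinear_family: unknown gating region ", g[[1]])
      idx <- resolve_connections(base, list(g[[2]]), "build_nonlinear_family")
      d[[j]][idx] <- 1L
    }
    model_spec(base$regions, base$a_support, base$c_support,
               d_supports = d,
               name = paste0("nonlinear_", names(variants)[k]))
  })
}

#' Read and write model specifications
#'
#' Model specs serialize to a structured-text (YAML) document holding the
#' name, region labels and explicit 0/1 support matrices; the round trip is
#' lossless.
#'
#' @param spec a `dcm_model_spec`.
#' @param path file path.
#' @return `read_model_spec` returns a `dcm_model_spec`;
#'   `write_model_spec` returns `path` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dcm_model_spec"))
  doc <- list(
    name = spec$name,
    regions = as.list(spec$regions$labels),
    a_support = mat_to_rows(spec$a_support),
    c_support = mat_to_rows(spec$c_support),
    b_supports = lapply(spec$b_supports, mat_to_rows),
    d_supports = lapply(spec$d_supports, mat_to_rows)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  regions <- region_set(unlist(doc$regions))
  model_spec(regions,
             rows_to_mat(doc$a_support),
             rows_to_mat(doc$c_support),
             b_supports = lapply(doc$b_supports, rows_to_mat),
             d_supports = lapply(doc$d_supports, rows_to_mat),
             name = doc$name)
}

mat_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.integer))
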