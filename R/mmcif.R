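# Minimal loop-aware PDBx/mmCIF reader.
#
# Parses the category tables this package needs (atom_site, entity,
# struct_ref, entity_src_gen, pdbx_struct_assembly_gen,
# pdbx_struct_oper_list, entry) from the first data block of a file.
# Handles loop_ tables, single key-value items, quoted values and
# semicolon-delimited multi-line text fields. Values "." and "?" are
# returned as NA.

# Split one mmCIF data line into tokens, honouring '...' and "..." quoting.
cif_tokenize <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(line, list(m))[[1]]
  quoted <- grepl("^'.*'$|^\".*\"$", toks)
  toks[quoted] <- substr(toks[quoted], 2, nchar(toks[quoted]) - 1L)
  toks
}

cif_na <- function(x) {
  x[x %in% c(".", "?")] <- NA_character_
  x
}

# Parse mmCIF text into a named list of data frames (one per category,
# all columns character) plus scalar categories as one-row data frames.
parse_mmcif_categories <- function(lines) {
  cats <- list()
  n <- length(lines)
  i <- 1L
  in_block <- FALSE

  read_value_tokens <- function(i, needed) {
    # Collect `needed` value tokens starting at line i; returns
    # list(tokens, next_i). Handles ;-delimited text blocks.
    toks <- character()
    while (length(toks) < needed && i <= n) {
      ln <- lines[i]
      if (startsWith(ln, ";")) {
        block <- sub("^;", "", ln)
        i <- i + 1L
        while (i <= n && !startsWith(lines[i], ";")) {
          block <- paste0(block, "\n", lines[i]); i <- i + 1L
        }
        i <- i + 1L  # closing ';'
        toks <- c(toks, block)
      } else if (grepl("^[[:space:]]*#", ln) || !nzchar(trimws(ln))) {
        i <- i + 1L
      } else {
        toks <- c(toks, cif_tokenize(ln))
        i <- i + 1L
      }
    }
    list(tokens = toks, next_i = i)
  }

  while (i <= n) {
    ln <- lines[i]
    tln <- trimws(ln)
    if (!nzchar(tln) || startsWith(tln, "#")) { i <- i + 1L; next }

    if (startsWith(tln, "data_")) {
      if (in_block) break  # first data block only
      in_block <- TRUE
      i <- i + 1L
      next
    }

    if (tln == "loop_") {
      i <- i + 1L
      cols <- character()
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        cols <- c(cols, trimws(cif_tokenize(lines[i])[1]))
        i <- i + 1L
      }
      if (!length(cols)) stop("mmCIF parse error: loop_ with no item names")
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", cols[1])
      item_names <- sub("^_[^.]+\\.", "", cols)
      values <- character()
      while (i <= n) {
        ln2 <- lines[i]
        tln2 <- trimws(ln2)
        if (!nzchar(tln2)) { i <- i + 1L; next }
        if (startsWith(tln2, "_") || tln2 == "loop_" ||
            startsWith(tln2, "data_") || startsWith(tln2, "#")) break
        if (startsWith(ln2, ";")) {
          block <- sub("^;", "", ln2); i <- i + 1L
          while (i <= n && !startsWith(lines[i], ";")) {
            block <- paste0(block, "\n", lines[i]); i <- i + 1L
          }
          i <- i + 1L
          values <- c(values, block)
        } else {
          values <- c(values, cif_tokenize(ln2))
          i <- i + 1L
        }
      }
      if (length(values) %% length(cols) != 0L)
        stop(sprintf(
          "mmCIF parse error in loop_ category '%s': %d values for %d columns",
          cat_name, length(values), length(cols)))
      mat <- matrix(cif_na(values), ncol = length(cols), byrow = TRUE)
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- item_names
      cats[[cat_name]] <- if (is.null(cats[[cat_name]])) df
                          else rbind(cats[[cat_name]], df)
      next
    }

    if (startsWith(tln, "_")) {
      toks <- cif_tokenize(tln)
      tag <- toks[1]
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", tag)
      item <- sub("^_[^.]+\\.", "", tag)
      if (length(toks) >= 2) {
        val <- toks[2]
        i <- i + 1L
      } else {
        r <- read_value_tokens(i + 1L, 1L)
        if (!length(r$tokens))
          stop(sprintf("mmCIF parse error: item '%s' has no value", tag))
        val <- r$tokens[1]
        i <- r$next_i
      }
      if (is.null(cats[[cat_name]]))
        cats[[cat_name]] <- data.frame(row.names = 1L)
      cats[[cat_name]][[item]] <- cif_na(val)
      next
    }

    stop("mmCIF parse error: unexpected content at line ", i, ": ", tln)
  }
  cats
}

# Parse an oper_expression like "1", "1,2", "(1-4)", "(1,2)(3,4)" into a
# list of operator-id sequences to compose (outer list = Cartesian product
# of parenthesised groups, applied left-to-right).
parse_oper_expression <- function(expr) {
  expr <- gsub("[[:space:]]", "", expr)
  groups <- if (grepl("^\\(", expr)) {
    m <- gregexpr("\\(([^()]*)\\)", expr)[[1]]
    vapply(regmatches(expr, list(m))[[1]],
           function(g) substr(g, 2, nchar(g) - 1L), character(1),
           USE.NAMES = FALSE)
  } else expr
  expand_group <- function(g) {
    unlist(lapply(strsplit(g, ",")[[1]], function(tok) {
      if (grepl("^[0-9]+-[0-9]+$", tok)) {
        rng <- as.integer(strsplit(tok, "-")[[1]])
        as.character(seq(rng[1], rng[2]))
      } else tok
    }), use.names = FALSE)
  }
  ids <- lapply(groups, expand_group)
  # Cartesian product across groups, preserving left-to-right application
  combos <- list(character())
  for (g in ids) {
    combos <- unlist(lapply(combos, function(pre)
      lapply(g, function(id) c(pre, id))), recursive = FALSE)
  }
  combos
}

# 3x4 affine operators from pdbx_struct_oper_list, keyed by operator id.
oper_matrices <- function(oper_df) {
  ops <- list()
  for (r in seq_len(nrow(oper_df))) {
    R <- matrix(as.numeric(c(
      oper_df[["matrix[1][1]"]][r], oper_df[["matrix[1][2]"]][r],
      oper_df[["matrix[1][3]"]][r],
      oper_df[["matrix[2][1]"]][r], oper_df[["matrix[2][2]"]][r],
      oper_df[["matrix[2][3]"]][r],
      oper_df[["matrix[3][1]"]][r], oper_df[["matrix[3][2]"]][r],
      oper_df[["matrix[3][3]"]][r])), nrow = 3, byrow = TRUE)
    t_vec <- as.numeric(c(oper_df[["vector[1]"]][r],
                          oper_df[["vector[2]"]][r],
                          oper_df[["vector[3]"]][r]))
    ops[[oper_df$id[r]]] <- list(R = R, t = t_vec)
  }
  ops
}

is_identity_oper <- function(op, tol = 1e-6) {
  all(abs(op$R - diag(3)) < tol) && all(abs(op$t) < tol)
}

compose_opers <- function(ops) {
  # mmCIF convention: in "(A)(B)" operator B is applied first, A last,
  # so compose right-to-left: x' = R_A (R_B x + t_B) + t_A
  R <- diag(3); t_vec <- c(0, 0, 0)
  for (op in rev(ops)) {
    R <- op$R %*% R
    t_vec <- op$R %*% t_vec + op$t
  }
  list(R = R, t = as.numeric(t_vec))
}
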