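# Parser for (atom-mapped) SMILES in the Daylight convention.
#
# Supported: the organic subset (B C N O P S F Cl Br I, aromatic b c n o s p),
# the wildcard "*", bracket atoms [<sym><@|@@><Hn><+n|-n><:map>], bond symbols
# - = # : / \, branches, ring closures (digits and %nn, reusable), and "."
# only at the species level (split before parsing).  Explicit [H] atoms and
# isotopes are not supported; hydrogens are carried as counts.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

parse_error <- function(fmt, ...) {
  stop(sprintf(paste0("SMILES parse error: ", fmt), ...), call. = FALSE)
}

# Parse one connected-or-not species string (no "."). Returns an rf_mol.
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    parse_error("empty species string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  symbol <- character(); aromatic <- logical(); charge <- integer()
  hcount <- integer(); map <- integer(); explicit_h <- logical()
  chir_written <- integer()
  wn <- list()          # written-order neighbour lists (0 = implicit-H slot)
  bonds <- list()
  ring <- list()        # open ring closures keyed by digit
  placeholder_seq <- 0L

  prev <- NA_integer_
  stack <- integer()
  pend_order <- NA_character_
  pend_dir <- 0L

  new_atom <- function(sym, arom, chg, h, mp, chir, expl_h) {
    symbol[length(symbol) + 1L] <<- sym
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hcount[length(hcount) + 1L] <<- h
    map[length(map) + 1L] <<- mp
    chir_written[length(chir_written) + 1L] <<- chir
    explicit_h[length(explicit_h) + 1L] <<- expl_h
    j <- length(symbol)
    wn[[j]] <<- integer()
    if (!is.na(prev)) {
      ord <- pend_order
      if (is.na(ord)) ord <- if (aromatic[prev] && arom) ":" else "-"
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = j, order = ord,
                                           dir = pend_dir)
      wn[[prev]] <<- c(wn[[prev]], j)
      wn[[j]] <<- c(wn[[j]], prev)
    }
    if (chir > 0L && h == 1L) wn[[j]] <<- c(wn[[j]], 0L)  # implicit-H slot
    if (chir > 0L && h > 1L)
      parse_error("chiral atom with more than one hydrogen near '%s'", sym)
    pend_order <<- NA_character_
    pend_dir <<- 0L
    prev <<- j
    invisible(j)
  }

  close_ring <- function(key) {
    rec <- ring[[key]]
    a <- rec$atom
    j <- prev
    if (a == j) parse_error("ring bond %s closes on its own atom", key)
    ord <- rec$order
    if (!is.na(pend_order)) {
      if (!is.na(ord) && ord != pend_order)
        parse_error("conflicting orders for ring bond %s", key)
      ord <- pend_order
    }
    if (is.na(ord)) ord <- if (aromatic[a] && aromatic[j]) ":" else "-"
    dir <- 0L
    if (rec$dir != 0L) dir <- rec$dir                 # oriented a -> j
    if (pend_dir != 0L) dir <- -pend_dir              # was oriented j -> a
    bonds[[length(bonds) + 1L]] <<- list(a1 = a, a2 = j, order = ord, dir = dir)
    wn[[a]][wn[[a]] == rec$placeholder] <<- j
    wn[[j]] <<- c(wn[[j]], a)
    ring[[key]] <<- NULL
    pend_order <<- NA_character_
    pend_dir <<- 0L
  }

  open_ring <- function(key) {
    placeholder_seq <<- placeholder_seq + 1L
    ph <- -placeholder_seq
    ring[[key]] <<- list(atom = prev, order = pend_order, dir = pend_dir,
                         placeholder = ph)
    wn[[prev]] <<- c(wn[[prev]], ph)
    pend_order <<- NA_character_
    pend_dir <<- 0L
  }

  handle_ring_digit <- function(key) {
    if (is.na(prev)) parse_error("ring bond %s before any atom", key)
    if (!is.null(ring[[key]])) close_ring(key) else open_ring(key)
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) parse_error("branch opened before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) parse_error("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pend_order <- ch
      i <- i + 1L
    } else if (ch == "/") {
      pend_order <- "-"; pend_dir <- 1L; i <- i + 1L
    } else if (ch == "\\") {
      pend_order <- "-"; pend_dir <- -1L; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      handle_ring_digit(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) parse_error("truncated %% ring closure")
      key <- paste0(chars[i + 1L], chars[i + 2L])
      if (!grepl("^[0-9]{2}$", key)) parse_error("bad ring closure '%%%s'", key)
      handle_ring_digit(key)
      i <- i + 3L
    } else if (ch == "[") {
      close_at <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "]") { close_at <- j; break }
        j <- j + 1L
      }
      if (is.na(close_at)) parse_error("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(close_at - 1L)], collapse = "")
      at <- parse_bracket_atom(body)
      new_atom(at$symbol, at$aromatic, at$charge, at$hcount, at$map,
               at$chirality, TRUE)
      i <- close_at + 1L
    } else if (ch == "*") {
      new_atom("*", FALSE, 0L, 0L, 0L, 0L, TRUE)
      i <- i + 1L
    } else if (ch == ".") {
      parse_error("'.' inside a species; split species before parsing")
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        new_atom(two, FALSE, 0L, NA_integer_, 0L, 0L, FALSE)
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        new_atom(ch, FALSE, 0L, NA_integer_, 0L, 0L, FALSE)
        i <- i + 1L
      } else if (ch %in% AROMATIC_SYMBOLS) {
        new_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, 0L, FALSE)
        i <- i + 1L
      } else {
        parse_error("unexpected token '%s' at position %d", ch, i)
      }
    }
  }
  if (length(stack)) parse_error("unmatched '('")
  if (length(ring)) parse_error("unclosed ring bond(s): %s",
                                paste(names(ring), collapse = ", "))
  if (!is.na(pend_order) || pend_dir != 0L)
    parse_error("dangling bond symbol at end of input")
  if (!length(symbol)) parse_error("no atoms in species")

  atoms <- data.frame(symbol = symbol, aromatic = aromatic, charge = charge,
                      hcount = hcount, map = map, parity = 0L,
                      stringsAsFactors = FALSE)
  bond_df <- if (length(bonds)) {
    data.frame(a1 = vapply(bonds, `[[`, 1L, "a1"),
               a2 = vapply(bonds, `[[`, 1L, "a2"),
               order = vapply(bonds, `[[`, "", "order"),
               dir = vapply(bonds, `[[`, 1L, "dir"),
               stringsAsFactors = FALSE)
  } else NULL
  mol <- new_mol(atoms, bond_df)

  # Implicit hydrogens on bare organic-subset atoms.
  bs <- mol_bondsum(mol)
  fill <- which(!explicit_h)
  if (length(fill)) {
    mol$atoms$hcount[fill] <- vapply(fill, function(k) {
      default_hcount(mol$atoms$symbol[k], bs[k])
    }, integer(1))
  }

  # Normalise written tetrahedral descriptors into the index frame.
  for (k in which(chir_written > 0L)) {
    frame_w <- wn[[k]]
    if (any(frame_w < 0L))
      parse_error("chiral atom %d has an unclosed ring neighbour", k)
    if (length(frame_w) != 4L)
      parse_error("cannot perceive tetrahedral stereo at atom %d (%d neighbours)",
                  k, length(frame_w))
    keys <- ifelse(frame_w == 0L, Inf, frame_w)
    frame_n <- frame_w[order(keys)]
    mol$atoms$parity[k] <- parity_rel(chir_written[k], frame_w, frame_n)
  }
  mol
}

parse_bracket_atom <- function(body) {
  m <- regexec(paste0(
    "^([0-9]+)?",                                   # isotope (rejected below)
    "(\\*|[A-Z][a-z]?|[bcnops])",                  # element
    "(@@|@)?",                                      # chirality
    "(?:H([0-9]*))?",                               # hydrogen count
    "(\\+[0-9]+|-[0-9]+|\\++|-+)?",                # charge
    "(?::([0-9]+))?$"                               # atom map
  ), body)[[1]]
  if (m[1] == -1L) parse_error("bad bracket atom '[%s]'", body)
  parts <- regmatches(body, list(regexec(paste0(
    "^([0-9]+)?(\\*|[A-Z][a-z]?|[bcnops])(@@|@)?(?:H([0-9]*))?",
    "(\\+[0-9]+|-[0-9]+|\\++|-+)?(?::([0-9]+))?$"), body)[[1]]))[[1]]
  iso <- parts[2]; sym <- parts[3]; chir <- parts[4]
  htxt <- parts[5]; ctxt <- parts[6]; mtxt <- parts[7]
  if (nzchar(iso)) parse_error("isotopes are not supported: '[%s]'", body)
  if (sym == "H") parse_error("explicit [H] atoms are not supported")
  arom <- sym %in% AROMATIC_SYMBOLS
  if (arom) sym <- toupper(sym)
  h <- if (identical(htxt, "")) {
    if (grepl("H", body, fixed = TRUE) &&
        grepl("H(?![a-z0-9])", body, perl = TRUE)) 1L else 0L
  } else as.integer(htxt)
  # The regex leaves htxt == "" both for absent H and bare "H"; disambiguate:
  if (identical(htxt, "") && !grepl("H($|[^a-z0-9])", body)) h <- 0L
  chg <- 0L
  if (nzchar(ctxt)) {
    if (grepl("^[+-][0-9]+$", ctxt)) {
      chg <- as.integer(ctxt)
    } else {
      chg <- nchar(ctxt) * (if (substr(ctxt, 1, 1) == "+") 1L else -1L)
    }
  }
  mp <- if (nzchar(mtxt)) as.integer(mtxt) else 0L
  chirality <- if (identical(chir, "@")) 1L else if (identical(chir, "@@")) 2L else 0L
  list(symbol = sym, aromatic = arom, charge = chg, hcount = h, map = mp,
       chirality = chirality)
}

# Parse a dot-separated list of species strings into a list of rf_mol.
parse_species <- function(text) {
  pieces <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (!length(pieces) || any(!nzchar(pieces)))
    parse_error("empty species in '%s'", text)
  lapply(pieces, parse_smiles)
}
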