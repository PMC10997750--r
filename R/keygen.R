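#' Fuzzy-extractor parameters
#'
#' The fuzzy extractor turns a noisy MinHash signature into a stable
#' secret key plus public helper data via a code-offset secure sketch
#' over a first-order Reed-Muller code RM(1, m) of length L = 2^m.
#' \code{t} is the decoding radius: any second reading within t bit flips
#' of the enrolled signature reproduces the identical key, while readings
#' beyond radius L/2 - t can at most land on a different key. The default
#' t = 63 at L = 256 is the largest radius with a uniqueness guarantee
#' (the code's minimum distance is L/2 = 128) and sits far above the
#' ~0.1 * L flips of typical like-input readings and far below the
#' ~0.5 * L flips of unlike readings.
#'
#' @param L signature/code length in bits; must be a power of 2.
#' @param t decode radius (maximum correctable bit errors); must satisfy
#'   \code{t <= L/4 - 1} so that decoding within radius t is unique.
#' @return A \code{cuf_fe_params} object.
#' @export
fe_params <- function(L = 256L, t = 63L) {
  L <- as.integer(L)
  m <- as.integer(round(log2(L)))
  if (2L^m != L || m < 2L)
    stop("L must be a power of 2 (>= 4)", call. = FALSE)
  if (t < 1L || t > L / 4L - 1L)
    stop("t must lie in [1, L/4 - 1] for unique decoding", call. = FALSE)
  structure(list(L = L, m = m, t = as.integer(t), key_bits = 256L,
                 fingerprint = sprintf("RM(1,%d);t=%d", m, t)),
            class = "cuf_fe_params")
}

sig_bits <- function(s, p) {
  if (length(s$bits) != p$L)
    stop("signature length does not match fuzzy-extractor parameters",
         call. = FALSE)
  as.integer(s$bits)
}

derive_key <- function(msg, salt) {
  digest::digest(paste0(paste(msg, collapse = ""), ":", salt),
                 algo = "sha256", serialize = FALSE)
}

#' Enroll a signature: generate key and helper data
#'
#' Code-offset construction: a uniformly random codeword c of the block
#' code is drawn; the public helper is the XOR offset signature + c (plus
#' a salt), and the 256-bit key is the SHA-256 hash of the codeword's
#' message together with the salt. For a linear code and uniform
#' codeword the offset alone is uniform, i.e., carries no information
#' about the signature beyond the code's residual entropy.
#'
#' @param s a \code{cuf_signature} of length \code{p$L}.
#' @param p a \code{cuf_fe_params}.
#' @param seed integer seed; the codeword and salt are deterministic
#'   functions of it.
#' @return A \code{cuf_key_bundle}: \code{key} (256-bit hex, secret),
#'   \code{helper} (public: offset bits, salt, fingerprints).
#' @export
fe_generate <- function(s, p = fe_params(), seed = 1L) {
  bits <- sig_bits(s, p)
  drawn <- with_seed(seed, list(
    msg = sample(0:1, p$m + 1L, replace = TRUE),
    salt = paste(sprintf("%02x", sample(0:255, 16L, replace = TRUE)),
                 collapse = "")))
  cw <- rm1_encode(drawn$msg, p$m)
  helper <- list(offset = bitwXor(bits, cw), salt = drawn$salt,
                 fe_fingerprint = p$fingerprint,
                 sig_fingerprint = s$fingerprint)
  structure(list(key = derive_key(drawn$msg, drawn$salt), helper = helper),
            class = "cuf_key_bundle")
}

#' @export
print.cuf_key_bundle <- function(x, ...) {
  cat("key bundle (", x$helper$fe_fingerprint, ")\n  key: ",
      x$key, "\n", sep = "")
  invisible(x)
}

#' Reproduce a key from a second, noisy signature
#'
#' Decodes \code{s2 XOR offset} with bounded-distance decoding. If the
#' second signature lies within the decode radius t of the enrolled one,
#' the original codeword -- and hence the identical key -- is recovered.
#' Beyond the radius, decoding either fails (returned as the value
#' \code{NA_character_}, not an error: "no match" is an ordinary outcome)
#' or lands on a different codeword and thus a different key.
#'
#' @param s2 a \code{cuf_signature}.
#' @param helper the public helper of a [fe_generate()] bundle (or the
#'   bundle itself).
#' @param p a \code{cuf_fe_params}; must match the helper's fingerprint.
#' @return The reproduced 256-bit key (hex) or \code{NA_character_} on
#'   decoding failure.
#' @export
fe_reproduce <- function(s2, helper, p = fe_params()) {
  if (inherits(helper, "cuf_key_bundle")) helper <- helper$helper
  if (!identical(helper$fe_fingerprint, p$fingerprint))
    stop("helper data was produced under different fuzzy-extractor parameters",
         call. = FALSE)
  if (!identical(helper$sig_fingerprint, s2$fingerprint))
    stop("signature parameters do not match the enrolled signature's",
         call. = FALSE)
  bits <- sig_bits(s2, p)
  dec <- rm1_decode(bitwXor(bits, helper$offset), p$m, p$t)
  if (!dec$ok) return(NA_character_)
  derive_key(dec$msg, helper$salt)
}

#' Classify a signature pair as same or different
#'
#' Enrolls \code{s1}, attempts key reproduction from \code{s2}, and
#' returns \code{"same"} iff the reproduced key equals the enrolled one.
#' This is the full-pipeline verdict on whether two responses stem from
#' the same challenge on the same pool.
#'
#' @param s1,s2 \code{cuf_signature}s of equal length.
#' @param p a \code{cuf_fe_params}.
#' @param seed seed for the enrollment codeword/salt.
#' @return \code{"same"} or \code{"different"}.
#' @export
classify_pair <- function(s1, s2, p = fe_params(), seed = 1L) {
  bundle <- fe_generate(s1, p, seed)
  key2 <- fe_reproduce(s2, bundle$helper, p)
  if (!is.na(key2) && identical(key2, bundle$key)) "same" else "different"
}

#' Write / read a key bundle as JSON
#'
#' @param bundle a \code{cuf_key_bundle}.
#' @param path file path.
#' @param include_key write the secret key too (default TRUE; set FALSE
#'   to store only the public helper).
#' @return \code{read_key_bundle} returns a \code{cuf_key_bundle} (with
#'   \code{key = NA} if it was withheld).
#' @export
write_key_bundle <- function(bundle, path, include_key = TRUE) {
  out <- if (include_key) list(key = bundle$key, helper = bundle$helper)
         else list(helper = bundle$helper)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_key_bundle
#' @export
read_key_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$helper$offset <- as.integer(x$helper$offset)
  structure(list(key = if (is.null(x$key)) NA_character_ else x$key,
                 helper = x$helper),
            class = "cuf_key_bundle")
}
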