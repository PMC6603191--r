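# Shared fixtures: literature parameter presets and an independent algebraic
# oracle for the two-impulse split-dose lethal-lesion count.

ago <- imk_presets("AGO1522")                       # idealized (a+c = 0 MF)
ago_lit <- imk_presets("AGO1522", idealized = FALSE)
du <- imk_presets("DU145")
g_if <- gamma_from_yd(4.393)
g_of <- gamma_from_yd(4.769)
half_field <- field_config(a_if = 0.5)
unif_field <- field_config(a_if = 1.0)

# w_T for two instantaneous fractions d1, d2 separated by tau (impulse limit)
split_w_oracle <- function(te, gamma, d1, d2, tau) {
  (te$alpha0 + gamma * te$beta0) * (d1 + d2) +
    te$beta0 * (d1^2 + d2^2) +
    2 * te$beta0 * d1 * d2 * exp(-te$a_plus_c * tau)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
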