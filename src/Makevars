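# keep IEEE semantics (no FMA contraction) so the scalar R reference engine
# reproduces the engine's arithmetic bit-for-bit
# -fno-builtin-sincos: keep cos/sin as separate libm calls (glibc sincos
# can differ from cos+sin by one ulp, breaking the equivalence contract)
PKG_CXXFLAGS = -ffp-contract=off -fno-builtin-sincos
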