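PKG_CPPFLAGS = -DARMA_NO_DEBUG
PKG_CXXFLAGS = -O3

# float32 network engine: allow FP reassociation and deeper unrolling so the
# convolution accumulators vectorize (CPU-specific code paths are emitted as
# target_clones and picked at load time); imageops.cpp (double-precision
# reference operations) keeps strict IEEE semantics.
unet.o: CXXFLAGS += -O3 -fno-math-errno -funsafe-math-optimizations -funroll-loops
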