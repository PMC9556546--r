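# The explicit-Euler integrator runs millions of small vectorisable steps;
# make sure the optimiser and SIMD vectoriser are on (some R builds put a
# plain -O2 after PKG_CXXFLAGS, so override CXXFLAGS outright).
CXXFLAGS = -O3 -fno-math-errno -funroll-loops -ftree-vectorize -mtune=generic -fPIC
PKG_CXXFLAGS = -O3 -fno-math-errno
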