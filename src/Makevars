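# appended after the site CXXFLAGS so the optimization flags take effect;
# the package is always compiled on the machine that runs it
override CXXFLAGS += -O3 -march=native -funroll-loops
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
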