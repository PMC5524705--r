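# FFTW3 backend for Armadillo's FFTs (library shipped alongside R in this toolchain)
PKG_CPPFLAGS = -DARMA_USE_FFTW3
PKG_LIBS = -L"$(R_HOME)/.." -lfftw3 $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
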