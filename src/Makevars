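# ViennaRNA (RNAlib) lives in the same prefix as R itself in this toolchain;
# derive the prefix from R.home() so the package compiles wherever that R runs.
RNA_PREFIX = $(shell "$(R_HOME)/bin/Rscript" --vanilla -e 'cat(normalizePath(file.path(R.home(), "..", "..")))')

PKG_CPPFLAGS = -I$(RNA_PREFIX)/include -pthread
PKG_LIBS = -L$(RNA_PREFIX)/lib -Wl,-rpath,$(RNA_PREFIX)/lib -lRNA -lgomp -lgsl -lgslcblas -lpthread -lmpfr -lgmp
CXX_STD = CXX17
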