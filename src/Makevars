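# The PELT hot loop is a long contiguous scan dominated by log(); allow the
# compiler to vectorise it.
PKG_CXXFLAGS = -ffast-math -ftree-vectorize
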