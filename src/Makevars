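# The conda-forge toolchain shipped with this R targets a sysroot glibc
# newer than the system loader, so its shared objects fail to load at
# install time.  Build with the system C++ compiler instead; `override`
# beats the later-read Makeconf assignments.
override CXX = /usr/bin/g++
override CXX17 = /usr/bin/g++
override CXXFLAGS = -O2 -Wall -fPIC
override CXX17FLAGS = -O2 -Wall -fPIC
override CXXPICFLAGS = -fPIC
override CXX17PICFLAGS = -fPIC
override SHLIB_CXXLDFLAGS = -shared
override SHLIB_CXX17LDFLAGS = -shared
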