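# apps that reach the foreground without implying active smartphone use
keyboard
gboard
launcher
systemui
system_ui
packageinstaller
permissioncontroller
inputmethod
lockscreen
setupwizard
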