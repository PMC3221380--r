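<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="stateDiff">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="upsert" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:simpleContent>
              <xs:extension base="xs:string">
                <xs:attribute name="path" type="xs:string" use="required"/>
                <xs:attribute name="type" use="required">
                  <xs:simpleType>
                    <xs:restriction base="xs:string">
                      <xs:enumeration value="number"/>
                      <xs:enumeration value="string"/>
                      <xs:enumeration value="boolean"/>
                    </xs:restriction>
                  </xs:simpleType>
                </xs:attribute>
              </xs:extension>
            </xs:simpleContent>
          </xs:complexType>
        </xs:element>
        <xs:element name="delete" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="path" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="baseRevision" type="xs:integer"/>
      <xs:attribute name="resync" type="xs:string"/>
      <xs:attribute name="newRevision" type="xs:integer" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
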